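#' Piecewise-constant demography
#'
#' A demographic history is a list of epochs, each with a start time in
#' generations ago and a constant haploid population size. The first epoch
#' starts at generation 0 and the last epoch extends indefinitely into the
#' past. All sizes are haploid internally; use `diploid = TRUE` to supply
#' diploid sizes (they are doubled, matching the haploid model with twice the
#' diploid count).
#'
#' @param start_gen nonnegative, strictly increasing integer start times in
#'   generations; the first must be 0.
#' @param size positive population sizes (> 1), one per epoch.
#' @param diploid if `TRUE`, `size` is in diploid individuals and is doubled.
#' @return an object of class `demography`: a data frame with columns
#'   `start_gen` and `size` (haploid).
#' @export
#' @examples
#' demography(c(0, 50), c(100, 10000))
#' constant_demography(2e5)
demography <- function(start_gen, size, diploid = FALSE) {
  if (length(start_gen) == 0L || length(start_gen) != length(size))
    stop("`start_gen` and `size` must be non-empty and of equal length")
  if (start_gen[1] != 0)
    stop("the first epoch must start at generation 0")
  if (any(start_gen < 0) || any(start_gen != floor(start_gen)))
    stop("`start_gen` must be nonnegative integers")
  if (length(start_gen) > 1 && any(diff(start_gen) <= 0))
    stop("`start_gen` must be strictly increasing")
  if (diploid) size <- 2 * size
  if (any(size <= 1)) stop("all population sizes must exceed 1")
  structure(data.frame(start_gen = as.numeric(start_gen),
                       size = as.numeric(size)),
            class = c("demography", "data.frame"))
}

#' @rdname demography
#' @export
constant_demography <- function(size, diploid = FALSE) {
  demography(0, size, diploid = diploid)
}

#' @rdname demography
#' @param x a `demography` object.
#' @return `pop_size_range()` returns `c(n1 = max size, n2 = min size)`, the
#'   extremes that bound moments under varying population size.
#' @export
pop_size_range <- function(x) {
  stopifnot(inherits(x, "demography"))
  c(n1 = max(x$size), n2 = min(x$size))
}

#' Read a demography from a JSON config
#'
#' The file holds a list of epochs, each `{"start_gen": g, "size_haploid": N}`
#' or `{"start_gen": g, "size_diploid": N}` (diploid sizes are doubled).
#'
#' @param path path to a JSON file.
#' @return a [demography] object.
#' @export
read_demography <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.list(cfg) && !is.data.frame(cfg) && !is.null(cfg$epochs))
    cfg <- cfg$epochs
  cfg <- as.data.frame(cfg)
  if (!is.null(cfg$size_haploid))
    demography(cfg$start_gen, cfg$size_haploid)
  else if (!is.null(cfg$size_diploid))
    demography(cfg$start_gen, cfg$size_diploid, diploid = TRUE)
  else stop("config must provide size_haploid or size_diploid")
}

is_constant <- function(dem) nrow(dem) == 1L
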