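#' Enumerate the allele-specific copy number class catalogue
#'
#' Lists every major/minor copy number pair `(A_M, A_m)` with
#' `A_M >= A_m >= 0` and `A_M + A_m <= t_max`, where `t_max` is the maximum
#' modelled total copy number. The ordering is deterministic — ascending
#' total copy number, ties broken by ascending minor copy number — so class
#' indices are stable across runs, checkpoints and serialised outputs.
#'
#' The class count equals `sum(pmin(0:t_max + 1, t_max - 0:t_max + 1))`.
#'
#' @param t_max Integer >= 0, maximum modelled total copy number.
#' @return An object of class `profile_catalog`: a list with `t_max`,
#'   `profiles` (data.frame with integer columns `a_major`, `a_minor`,
#'   `total`) and `j`, the number of classes.
#' @examples
#' enumerate_profiles(2)   # the four diploid-regime classes
#' enumerate_profiles(8)$j # 25
#' @export
enumerate_profiles <- function(t_max) {
  if (length(t_max) != 1L || is.na(t_max) || t_max < 0 || t_max != floor(t_max))
    stop("t_max must be a single non-negative integer")
  t_max <- as.integer(t_max)
  rows <- list()
  for (tot in 0:t_max) {
    for (am in 0:(tot %/% 2L)) {
      rows[[length(rows) + 1L]] <- c(tot - am, am)
    }
  }
  m <- do.call(rbind, rows)
  profiles <- data.frame(
    a_major = as.integer(m[, 1L]),
    a_minor = as.integer(m[, 2L]),
    total = as.integer(m[, 1L] + m[, 2L])
  )
  structure(
    list(t_max = t_max, profiles = profiles, j = nrow(profiles)),
    class = "profile_catalog"
  )
}

#' @export
print.profile_catalog <- function(x, ...) {
  cat(sprintf("Copy number class catalogue: t_max = %d, J = %d classes\n",
              x$t_max, x$j))
  print(x$profiles)
  invisible(x)
}

#' Map major/minor copy number pairs to catalogue class indices
#'
#' @param a_major,a_minor Integer vectors of major/minor copy numbers.
#' @param catalog A `profile_catalog`.
#' @return Integer vector of 1-based class indices.
#' @export
profile_index <- function(a_major, a_minor, catalog) {
  stopifnot(inherits(catalog, "profile_catalog"))
  key <- paste(a_major, a_minor)
  ref <- paste(catalog$profiles$a_major, catalog$profiles$a_minor)
  idx <- match(key, ref)
  if (anyNA(idx))
    stop("copy number pair outside the catalogue (check t_max and A_M >= A_m)")
  idx
}
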