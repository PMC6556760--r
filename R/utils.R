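#' Derive a reproducible child seed from a master seed
#'
#' Replicate `i` of a Monte-Carlo run is seeded with `child_seed(master, i)`
#' so that increasing the number of replicates never reshuffles the seeds of
#' the replicates already run. The scheme is a fixed Lehmer-style mixing of
#' the master seed and the replicate index modulo 2^31 - 1; it is documented
#' here as part of the reproducibility contract and is stable across package
#' versions.
#'
#' @param master integer master seed.
#' @param i replicate index (1-based).
#' @return an integer in `[1, 2^31 - 1]`, usable with [set.seed()].
#' @export
child_seed <- function(master, i) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(master) %% m) + 1
  as.integer(((s * 48271 + as.numeric(i) * 96443) %% (m - 1)) + 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lo = -Inf, hi = Inf,
                             open_lo = FALSE, open_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop_field(field, sprintf("must be in %s%s, %s%s",
                              if (open_lo) "(" else "[", format(lo),
                              format(hi), if (open_hi) ")" else "]"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
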