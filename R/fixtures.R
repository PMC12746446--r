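#' Synthetic dU/dlambda series with known diagnostic ground truth
#'
#' Deterministic generators for the diagnostic test-bench:
#'
#' * `"iid"`: white noise; statistical inefficiency `g = 1`, so
#'   `SE = sd / sqrt(n)`.
#' * `"ar1"`: a stationary AR(1) process `x_t = mean + phi (x_{t-1} - mean) +
#'   eps_t`; its integrated autocorrelation gives `g = (1 + phi) / (1 - phi)`.
#' * `"dual_well_replicates"`: `n_replicates` series of which half fluctuate
#'   tightly around `+well_mean` and half around `-well_mean` -- the
#'   positive control for the sampling-quality diagnostic (tiny within-run
#'   SE, large across-replicate spread, ratio far above 2).
#'
#' @param kind `"iid"`, `"ar1"`, or `"dual_well_replicates"`.
#' @param params named list of parameters: `n` (series length), `mean`, `sd`
#'   (innovation sd for `"ar1"`), `phi` (AR coefficient, `|phi| < 1`),
#'   `n_replicates`, `well_mean`, `within_sd`.
#' @param seed integer seed (mandatory; output is deterministic given it).
#' @param file optional path; if given, the table is also written as CSV.
#' @return a data frame: columns `step` and `value` (and `replicate` for
#'   `"dual_well_replicates"`). Ground-truth quantities are attached as
#'   attribute `"truth"`.
#' @export
generate_fixture <- function(kind = c("iid", "ar1", "dual_well_replicates"),
                             params = list(), seed, file = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(seed), length(seed) == 1)
  p <- utils::modifyList(
    switch(kind,
           iid = list(n = 1e5, mean = 0, sd = 1),
           ar1 = list(n = 1e5, mean = 0, sd = 1, phi = 0.9),
           dual_well_replicates = list(n = 1000, n_replicates = 8,
                                       well_mean = 1, within_sd = 0.05)),
    params)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  out <- switch(kind,
    iid = {
      x <- stats::rnorm(p$n, p$mean, p$sd)
      structure(data.frame(step = seq_len(p$n), value = x),
                truth = list(g = 1, se = p$sd / sqrt(p$n)))
    },
    ar1 = {
      if (abs(p$phi) >= 1) stop("AR(1) coefficient must satisfy |phi| < 1",
                                call. = FALSE)
      x <- p$mean + as.numeric(
        stats::arima.sim(model = list(ar = p$phi), n = p$n, sd = p$sd))
      structure(data.frame(step = seq_len(p$n), value = x),
                truth = list(g = (1 + p$phi) / (1 - p$phi),
                             var = p$sd^2 / (1 - p$phi^2)))
    },
    dual_well_replicates = {
      nr <- p$n_replicates
      stopifnot(nr >= 2)
      sign <- rep(c(1, -1), length.out = nr)
      d <- do.call(rbind, lapply(seq_len(nr), function(r)
        data.frame(replicate = r, step = seq_len(p$n),
                   value = sign[r] * p$well_mean +
                     stats::rnorm(p$n, 0, p$within_sd))))
      structure(d, truth = list(sigma_across = stats::sd(sign * p$well_mean),
                                expected_flag = "severe"))
    })
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}
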