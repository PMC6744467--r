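# Mixed-effects stages: random-intercept LMMs (speed ~ time, AEI ~ ST) and
# 30-minute-interval comparisons of exploration with Tukey-adjusted
# pairwise contrasts.

#' Fit a random-intercept linear mixed model
#'
#' Wraps `lme4::lmer` with random intercepts for each grouping factor, REML
#' estimation, and a Wald coefficient table. p-values use the normal
#' approximation to the t statistic (no Satterthwaite machinery in the
#' dependency set); with the sample sizes of tracking datasets the
#' difference is negligible. Singular fits are reported, not dropped.
#'
#' @param data data.frame with the named columns.
#' @param response response column name.
#' @param fixed character vector of fixed-effect column names (or terms).
#' @param random_groups character vector of grouping-factor column names;
#'   each must have at least 2 levels.
#' @return object of class `lmm_result`: `model`, `coefficients`
#'   (data.frame estimate/se/t/p), `ranef_var`, `singular`, `nobs`,
#'   `diagnostics` (fitted and residuals, for homoscedasticity checks).
#' @export
fit_lmm <- function(data, response, fixed, random_groups) {
  need <- c(response, setdiff(all.vars(stats::reformulate(fixed)), "."),
            random_groups)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (g in random_groups) {
    if (length(unique(data[[g]])) < 2)
      stop("random grouping factor '", g, "' has fewer than 2 levels")
    data[[g]] <- factor(data[[g]])
  }
  fml <- stats::as.formula(paste(
    response, "~", paste(fixed, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", random_groups), collapse = " + ")))
  model <- lme4::lmer(fml, data = data, REML = TRUE)
  singular <- lme4::isSingular(model)
  if (singular)
    message("mixed model fit is singular (a variance component is ~0)")
  est <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  tval <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), t = unname(tval),
                      p = 2 * pnorm(-abs(unname(tval))))
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(list(model = model, coefficients = coefs,
                 ranef_var = vc[, c("grp", "vcov", "sdcor")],
                 singular = singular, nobs = stats::nobs(model),
                 diagnostics = data.frame(fitted = stats::fitted(model),
                                          residual = stats::resid(model))),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> n=%d%s\n", x$nobs,
              if (x$singular) " (singular fit)" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

# clock-aligned 30-minute interval start (seconds since midnight, unwrapped)
.interval_start <- function(clock_s, width_s = 1800) floor(clock_s / width_s) * width_s

#' Compare exploration across 30-minute intervals
#'
#' Bins trajectories into clock-aligned 30-minute intervals (19:30, 20:00,
#' ...), fits a random-intercept LMM of the response on the interval factor
#' (cell-means coding) with colony and date intercepts, and returns all
#' pairwise interval contrasts with Tukey-adjusted p-values (studentized
#' range on the Wald statistics). Intervals with fewer than 2 observations
#' are dropped with a warning.
#'
#' @param records data.frame with columns `clock_s` (seconds), the response,
#'   and the grouping columns.
#' @param response response column name (default `"AEI"`).
#' @param random_groups grouping-factor column names (default
#'   `c("colony", "date")`).
#' @return list `means` (per-interval estimated mean, se, n), `contrasts`
#'   (data.frame with Tukey-adjusted p), `model` (`lmm_result`-like),
#'   `intervals` (labels in time order).
#' @export
interval_comparison <- function(records, response = "AEI",
                                random_groups = c("colony", "date")) {
  need <- c("clock_s", response, random_groups)
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  records$interval_s <- .interval_start(records$clock_s)
  cnt <- table(records$interval_s)
  small <- names(cnt)[cnt < 2]
  if (length(small)) {
    warning("dropping interval(s) with < 2 observations: ",
            paste(.s_to_clock(as.numeric(small)), collapse = ", "))
    records <- records[!records$interval_s %in% as.numeric(small), ,
                       drop = FALSE]
  }
  ivs <- sort(unique(records$interval_s))
  if (length(ivs) < 2) stop("need at least 2 populated intervals")
  labels <- .s_to_clock(ivs)
  records$interval <- factor(.s_to_clock(records$interval_s),
                             levels = labels)
  for (g in random_groups) records[[g]] <- factor(records[[g]])
  fml <- stats::as.formula(paste(
    response, "~ 0 + interval +",
    paste(sprintf("(1 | %s)", random_groups), collapse = " + ")))
  model <- lme4::lmer(fml, data = records, REML = TRUE)
  est <- lme4::fixef(model)
  V <- as.matrix(stats::vcov(model))
  k <- length(est)
  means <- data.frame(interval = labels, estimate = unname(est),
                      se = sqrt(diag(V)),
                      n = as.integer(table(records$interval)))
  dfres <- stats::nobs(model) - k
  pairs <- utils::combn(k, 2)
  contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    d <- est[i] - est[j]
    sed <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    tval <- d / sed
    data.frame(contrast = paste(labels[i], "-", labels[j]),
               estimate = unname(d), se = sed, t = unname(tval),
               p_tukey = ptukey(sqrt(2) * abs(unname(tval)), nmeans = k,
                                df = dfres, lower.tail = FALSE))
  }))
  list(means = means, contrasts = contrasts, model = model,
       intervals = labels)
}
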