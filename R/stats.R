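#' Wilcoxon rank-sum test with effect size
#'
#' Rank-sum test on two independent samples using midranks for ties and
#' (by default) the normal approximation with continuity correction and
#' tie-corrected variance; `effect_r = |Z| / sqrt(n_x + n_y)`. For
#' small samples an exact two-sided p by complete enumeration of rank
#' assignments is available.
#'
#' @param x,y Numeric score vectors (each nonempty).
#' @param exact Use exact enumeration (feasible for <= 10 per group).
#' @return One-row tibble: `W` (rank sum of `x`), `U` (Mann-Whitney
#'   statistic, the convention of `wilcox.test`), `z`, `p`, `effect_r`,
#'   `method`.
#' @export
wilcoxon_ranksum <- function(x, y, exact = FALSE) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups need at least one observation", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))                       # midranks
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (exact) {
    if (choose(n, nx) > 2e6) stop("exact enumeration infeasible at this n", call. = FALSE)
    combs <- utils::combn(n, nx)
    Ws <- colSums(matrix(r[combs], nrow = nx))
    mu <- nx * (n + 1) / 2
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
    z <- NA_real_
    er <- abs(W - mu) / sqrt(sum((Ws - mu)^2) / length(Ws)) / sqrt(n)
    return(tibble::tibble(W = W, U = U, z = z, p = p, effect_r = er,
                          method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  cc <- sign(W - mu) * 0.5
  z <- (W - mu - cc) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  p <- min(1, p)
  tibble::tibble(W = W, U = U, z = z, p = p,
                 effect_r = abs(z) / sqrt(n), method = "normal")
}

#' Flag score outliers beyond k standard deviations
#'
#' @param scores Numeric vector (>= 3 values).
#' @param k SD multiplier (default 3).
#' @return Integer indices of scores with `|score - mean| > k * SD`;
#'   empty when the variance is zero.
#' @export
detect_score_outliers <- function(scores, k = 3) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 3L) stop("need at least 3 scores", call. = FALSE)
  s <- stats::sd(scores)
  if (s == 0) return(integer(0))
  which(abs(scores - mean(scores)) > k * s)
}

model_family_terms <- function(family) {
  switch(family,
    dwpli = c("dwpli_mean"),
    segregation = c("clustering", "modularity"),
    smallworld = c("small_world"),
    integration = c("path_length"),
    stop("unknown model family: ", family, call. = FALSE)
  )
}

#' Fit one verbal-fluency regression model
#'
#' OLS with the family's graph metrics as z-scaled numeric predictors,
#' treatment-coded age group (reference: younger) and sex (reference:
#' female), each metric's interaction with age group, and sex as a
#' covariate:
#' \itemize{
#'   \item `dwpli`: `outcome ~ dwpli * age + sex`
#'   \item `segregation`: `outcome ~ clustering * age + modularity * age + sex`
#'   \item `smallworld`: `outcome ~ small_world * age + sex`
#'   \item `integration`: `outcome ~ path_length * age + sex`
#' }
#' Rows with a missing metric or outcome are excluded listwise; scaling
#' happens on the analysis rows before any leverage filtering.
#'
#' @param table Analysis tibble with columns `age_group`, `sex`, the
#'   outcome, and the family's metric columns (one band's values).
#' @param family One of `"dwpli"`, `"segregation"`, `"smallworld"`,
#'   `"integration"`.
#' @param band Band label carried into the summary.
#' @param outcome `"semantic_fluency"` or `"letter_fluency"`.
#' @param ref_age,ref_sex Reference (treatment-contrast) levels;
#'   the analysis convention is younger / female.
#' @return A `fluency_model`: the `lm` fit plus metadata (`model_id`,
#'   `family`, `band`, `outcome`, `n_used`, `n_leverage_removed`,
#'   `data`).
#' @export
fit_model <- function(table, family = c("dwpli", "segregation",
                                        "smallworld", "integration"),
                      band = NA_character_,
                      outcome = c("semantic_fluency", "letter_fluency"),
                      ref_age = "younger", ref_sex = "female") {
  family <- match.arg(family)
  outcome <- match.arg(outcome)
  metrics <- model_family_terms(family)
  need <- c(outcome, "age_group", "sex", metrics)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  d <- table[stats::complete.cases(table[, need]), need, drop = FALSE]
  p_terms <- 2L * length(metrics) + 2L          # metrics + interactions + age + sex
  if (nrow(d) < p_terms + 2L) {
    stop("too few complete rows to fit the model", call. = FALSE)
  }
  d$age_group <- stats::relevel(factor(d$age_group), ref = ref_age)
  d$sex <- stats::relevel(factor(d$sex), ref = ref_sex)
  for (m in metrics) d[[m]] <- as.numeric(scale(d[[m]]))
  rhs <- paste(c(paste0(metrics, " * age_group"), "sex"), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::lm(fml, data = d)
  if (fit$rank < ncol(stats::model.matrix(fit))) {
    mm <- stats::model.matrix(fit)
    aliased <- colnames(mm)[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  structure(
    list(fit = fit, model_id = paste(family, band, outcome, sep = "."),
         family = family, band = band, outcome = outcome,
         n_used = nrow(d), n_leverage_removed = 0L, data = d),
    class = "fluency_model"
  )
}

#' @export
print.fluency_model <- function(x, ...) {
  cat(sprintf("<fluency_model> %s (n = %d, %d leverage rows removed)\n",
              x$model_id, x$n_used, x$n_leverage_removed))
  print(tidy(x), ...)
  invisible(x)
}

#' Remove leverage points and refit
#'
#' Observations whose hat-matrix diagonal exceeds `2 (p + 1) / n` —
#' with `p` the number of non-intercept predictors — are removed in a
#' single pass and the model refit on the remaining rows (predictors
#' are not re-scaled). Only the refit is meant to be reported.
#'
#' @param model A `fluency_model`.
#' @return The refit `fluency_model` with `n_leverage_removed` set.
#' @export
leverage_filter_refit <- function(model) {
  stopifnot(inherits(model, "fluency_model"))
  h <- stats::hatvalues(model$fit)
  p1 <- ncol(stats::model.matrix(model$fit))      # p + 1 incl. intercept
  thr <- 2 * p1 / length(h)
  drop_idx <- which(h > thr)
  if (length(drop_idx) == 0L) return(model)
  d <- model$data[-drop_idx, , drop = FALSE]
  if (nrow(d) < p1 + 1L) {
    stop("leverage filtering left too few rows to refit", call. = FALSE)
  }
  refit <- stats::lm(stats::formula(model$fit), data = d)
  out <- model
  out$fit <- refit
  out$data <- d
  out$n_used <- nrow(d)
  out$n_leverage_removed <- model$n_leverage_removed + length(drop_idx)
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy coefficient table of a fluency model
#'
#' @param x A `fluency_model`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` (the Estimate / SE / t / p layout of a regression
#'   summary table).
#' @method tidy fluency_model
#' @export
tidy.fluency_model <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = unname(co[, 1L]),
                 std.error = unname(co[, 2L]), statistic = unname(co[, 3L]),
                 p.value = unname(co[, 4L]))
}

#' One-row model summary of a fluency model
#'
#' @param x A `fluency_model`.
#' @param ... Unused.
#' @return Tibble: `model_id`, `family`, `band`, `outcome`,
#'   `adj.r.squared`, `statistic` (overall F), `df`, `df.residual`,
#'   `p.value`, `n_used`, `n_leverage_removed`.
#' @method glance fluency_model
#' @export
glance.fluency_model <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(
    model_id = x$model_id, family = x$family, band = x$band,
    outcome = x$outcome,
    adj.r.squared = s$adj.r.squared,
    statistic = unname(f[1L]), df = unname(f[2L]),
    df.residual = unname(f[3L]),
    p.value = unname(stats::pf(f[1L], f[2L], f[3L], lower.tail = FALSE)),
    n_used = x$n_used, n_leverage_removed = x$n_leverage_removed
  )
}

#' Run the full model grid: 4 families x 4 bands x 2 outcomes
#'
#' Fits every family/band/outcome combination, applies the leverage
#' filter once, and returns the refit models. No multiple-testing
#' correction is applied. Bands absent from the table are skipped with
#' a warning.
#'
#' @param metrics Wide per-subject x band metrics tibble
#'   ([graph_metric_record()] rows).
#' @param behavioural Tibble with `subject_id`, `age_group`, `sex`,
#'   `semantic_fluency`, `letter_fluency`.
#' @param bands Bands to model.
#' @param leverage_filter Apply [leverage_filter_refit()] (default).
#' @return List of `fluency_model` objects, named by `model_id`.
#' @export
run_all_models <- function(metrics, behavioural,
                           bands = c("delta", "theta", "alpha", "beta"),
                           leverage_filter = TRUE) {
  out <- list()
  for (b in bands) {
    mb <- metrics[as.character(metrics$band) == b, , drop = FALSE]
    if (nrow(mb) == 0L) {
      warning("no metrics for band '", b, "'; its models are skipped",
              call. = FALSE)
      next
    }
    tab <- dplyr::inner_join(behavioural, mb, by = "subject_id")
    for (fam in c("dwpli", "segregation", "smallworld", "integration")) {
      for (oc in c("semantic_fluency", "letter_fluency")) {
        m <- tryCatch({
          m <- fit_model(tab, family = fam, band = b, outcome = oc)
          if (leverage_filter) m <- leverage_filter_refit(m)
          m
        }, error = function(e) {
          warning("model ", paste(fam, b, oc, sep = "."), " skipped: ",
                  conditionMessage(e), call. = FALSE)
          NULL
        })
        if (!is.null(m)) out[[m$model_id]] <- m
      }
    }
  }
  out
}

#' Bind model summaries into the on-disk table layout
#'
#' @param models List of `fluency_model` objects.
#' @return Tibble with one row per coefficient: `model_id`, `family`,
#'   `band`, `outcome`, then `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `n_used`, `n_leverage_removed`.
#' @export
model_summary_table <- function(models) {
  purrr::map_dfr(models, function(m) {
    dplyr::mutate(tidy(m), model_id = m$model_id, family = m$family,
                  band = m$band, outcome = m$outcome, n_used = m$n_used,
                  n_leverage_removed = m$n_leverage_removed,
                  .before = 1L)
  })
}
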