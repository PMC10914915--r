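#' Multi-environment backward elimination of candidate clusters
#'
#' Fits the genotype-by-environment adjusted means of one trait as
#' `value = environment + sum_c environment:carrier(c) + genotype(random)
#' + residual`, where `carrier(c)` is the 0/1 B73-allele indicator at the
#' peak marker of candidate cluster `c`, so each candidate carries one
#' fixed allele effect per environment. Each candidate is tested by a
#' joint Wald test of its full set of environment effects when added last
#' (from the fixed-effect covariance of the current model); the candidate
#' with the largest p is removed and the model refitted, until every
#' remaining candidate satisfies `p <= alpha`. Survivors are QTLs;
#' per-environment effects, standard errors and Wald tests come from the
#' final model.
#'
#' Candidates with identical carrier vectors are collinear: the one with
#' the smaller single-candidate joint p is kept, the other dropped and
#' recorded.
#'
#' @param candidates data.frame with columns `id` and `marker` (peak
#'   markers; duplicated markers are deduplicated).
#' @param means data.frame `genotype`, `environment`, `value` of adjusted
#'   means across environments.
#' @param panel a [MagicPanel-class].
#' @param alpha retention level for the joint Wald test (default 0.01).
#' @param effectAlpha level for the a-posteriori per-environment Wald
#'   tests (default `alpha`).
#' @return list of class `qtlSelection`: `selected` (ids), `joint`
#'   (id, marker, joint statistic, df, p at the final model), `effects`
#'   (id, environment, beta, se, p, significant), `dropped`
#'   (id, reason, p), `trace` (elimination order).
#' @export
backwardSelectQtls <- function(candidates, means, panel, alpha = 0.01,
                               effectAlpha = alpha) {
  empty <- list(selected = character(),
                joint = data.frame(id = character(), marker = character(),
                                   statistic = numeric(), df = integer(),
                                   p = numeric()),
                effects = data.frame(id = character(),
                                     environment = character(),
                                     beta = numeric(), se = numeric(),
                                     p = numeric(),
                                     significant = logical()),
                dropped = data.frame(id = character(), reason = character(),
                                     p = numeric()),
                trace = character())
  class(empty) <- "qtlSelection"
  if (is.null(candidates) || !nrow(candidates)) return(empty)
  candidates <- candidates[!duplicated(candidates$marker), , drop = FALSE]
  candidates <- candidates[order(candidates$marker), , drop = FALSE]
  stopifnot(all(candidates$marker %in% rownames(panel)))

  d <- means[is.finite(means$value), ]
  d$environment <- factor(d$environment)
  d$genotype <- as.character(d$genotype)
  B <- b73Dosage(panel)
  stopifnot(all(d$genotype %in% rownames(B)))
  nEnv <- nlevels(d$environment)

  ## carrier columns; drop monomorphic and resolve collinear candidates
  X <- B[d$genotype, candidates$marker, drop = FALSE]
  colnames(X) <- paste0("cand_", seq_len(nrow(candidates)))
  dropped <- empty$dropped
  mono <- apply(X, 2, stats::var) == 0
  if (any(mono)) {
    dropped <- rbind(dropped, data.frame(
      id = candidates$id[mono], reason = "monomorphic", p = NA_real_))
    candidates <- candidates[!mono, , drop = FALSE]
    X <- X[, !mono, drop = FALSE]
  }
  if (!nrow(candidates)) return(empty)
  dup <- duplicated(t(X))
  if (any(dup)) {
    keyOf <- apply(X, 2, paste, collapse = "")
    for (k in unique(keyOf[dup])) {
      ix <- which(keyOf == k)
      ps <- vapply(ix, function(i)
        jointWaldSingle(d, X[, i]), numeric(1))
      lose <- ix[-which.min(ps)]
      dropped <- rbind(dropped, data.frame(
        id = candidates$id[lose], reason = "collinear",
        p = ps[match(lose, ix)]))
    }
    keep <- !(candidates$id %in%
                dropped$id[dropped$reason == "collinear"])
    candidates <- candidates[keep, , drop = FALSE]
    X <- X[, keep, drop = FALSE]
  }

  active <- seq_len(nrow(candidates))
  trace <- character()
  fitModel <- function(ix) {
    dat <- cbind(d, X[, ix, drop = FALSE])
    terms <- colnames(X)[ix]
    rhs <- c("0 + environment",
             paste0("environment:", terms),
             "(1 | genotype)")
    suppressMessages(suppressWarnings(lme4::lmer(
      stats::reformulate(rhs, response = "value"), data = dat,
      REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))))
  }
  waldJoint <- function(fit, term) {
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    ix <- grep(paste0(":", term, "$"), names(fe))
    ix <- ix[!is.na(fe[ix])]
    if (!length(ix)) return(c(stat = 0, df = 0, p = 1))
    b <- fe[ix]
    st <- tryCatch(as.numeric(crossprod(b, solve(V[ix, ix], b))),
                   error = function(e) NA_real_)
    if (!is.finite(st)) return(c(stat = 0, df = length(ix), p = 1))
    c(stat = st, df = length(ix),
      p = stats::pchisq(st, df = length(ix), lower.tail = FALSE))
  }
  finalFit <- NULL
  while (length(active)) {
    fit <- fitModel(active)
    tests <- t(vapply(colnames(X)[active], function(tm) waldJoint(fit, tm),
                      numeric(3)))
    worst <- which.max(tests[, "p"])
    if (tests[worst, "p"] > alpha) {
      trace <- c(trace, candidates$id[active[worst]])
      dropped <- rbind(dropped, data.frame(
        id = candidates$id[active[worst]], reason = "eliminated",
        p = tests[worst, "p"]))
      active <- active[-worst]
    } else {
      finalFit <- fit
      break
    }
  }
  if (!length(active)) {
    empty$dropped <- dropped
    empty$trace <- trace
    return(empty)
  }
  tests <- t(vapply(colnames(X)[active],
                    function(tm) waldJoint(finalFit, tm), numeric(3)))
  joint <- data.frame(id = candidates$id[active],
                      marker = candidates$marker[active],
                      statistic = tests[, "stat"],
                      df = as.integer(tests[, "df"]), p = tests[, "p"],
                      stringsAsFactors = FALSE)
  fe <- lme4::fixef(finalFit)
  V <- as.matrix(stats::vcov(finalFit))
  envLevels <- levels(d$environment)
  effects <- do.call(rbind, lapply(seq_along(active), function(k) {
    tm <- colnames(X)[active[k]]
    rows <- lapply(envLevels, function(e) {
      nm <- paste0("environment", e, ":", tm)
      if (!nm %in% names(fe) || is.na(fe[nm]))
        return(data.frame(id = candidates$id[active[k]], environment = e,
                          beta = NA_real_, se = NA_real_, p = NA_real_,
                          significant = NA))
      b <- fe[[nm]]; se <- sqrt(V[nm, nm])
      p <- stats::pchisq((b / se)^2, df = 1, lower.tail = FALSE)
      data.frame(id = candidates$id[active[k]], environment = e,
                 beta = b, se = se, p = p,
                 significant = p <= effectAlpha)
    })
    do.call(rbind, rows)
  }))
  structure(list(selected = candidates$id[active], joint = joint,
                 effects = effects, dropped = dropped, trace = trace,
                 model = finalFit),
            class = "qtlSelection")
}

## joint Wald p of one candidate alone (used to resolve collinear pairs)
jointWaldSingle <- function(d, x) {
  dat <- cbind(d, cand = x)
  fit <- suppressMessages(suppressWarnings(lme4::lmer(
    value ~ 0 + environment + environment:cand + (1 | genotype),
    data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE))))
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  ix <- grep(":cand$", names(fe))
  b <- fe[ix]
  st <- as.numeric(crossprod(b, solve(V[ix, ix], b)))
  stats::pchisq(st, df = length(ix), lower.tail = FALSE)
}

#' @export
print.qtlSelection <- function(x, ...) {
  cat("backward selection:", length(x$selected), "QTL retained,",
      nrow(x$dropped), "candidate(s) dropped\n")
  if (nrow(x$joint)) print(x$joint[, c("id", "marker", "p")])
  invisible(x)
}

#' Phenotypic variance explained by QTL peak markers
#'
#' Per environment, `r2 = 1 - RSS(regression on the peak carriers) /
#' RSS(intercept only)` on the adjusted means; at the network scale the
#' adjusted means are environment-centred first and all peaks fitted
#' jointly. Per-QTL partial r2 is the leave-one-out difference from the
#' full model.
#'
#' @param markers peak marker names.
#' @param means data.frame `genotype`, `environment`, `value`.
#' @param panel a [MagicPanel-class].
#' @param scope `"network"` or `"per-environment"`.
#' @return for `"network"`: list with `r2` and `partial` (named per-QTL
#'   leave-one-out r2 differences); for `"per-environment"`: data.frame
#'   `environment`, `r2`.
#' @export
varianceExplained <- function(markers, means, panel,
                              scope = c("network", "per-environment")) {
  scope <- match.arg(scope)
  stopifnot(length(markers) >= 1)
  d <- means[is.finite(means$value), ]
  B <- b73Dosage(panel)[d$genotype, markers, drop = FALSE]
  r2Of <- function(y, Xm) {
    rss0 <- sum((y - mean(y))^2)
    fit <- stats::lm.fit(cbind(1, Xm), y)
    1 - sum(fit$residuals^2) / rss0
  }
  if (scope == "per-environment") {
    envs <- unique(d$environment)
    data.frame(environment = envs,
               r2 = vapply(envs, function(e) {
                 sel <- d$environment == e
                 r2Of(d$value[sel], B[sel, , drop = FALSE])
               }, numeric(1)), row.names = NULL)
  } else {
    y <- d$value - stats::ave(d$value, d$environment)
    full <- r2Of(y, B)
    partial <- vapply(seq_along(markers), function(k) {
      if (length(markers) == 1L) return(full)
      full - r2Of(y, B[, -k, drop = FALSE])
    }, numeric(1))
    list(r2 = full, partial = stats::setNames(partial, markers))
  }
}
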