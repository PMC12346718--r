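#' Shapiro-Wilk normality screen
#'
#' Standard Shapiro-Wilk test with explicit handling of the degenerate
#' cases: fewer than 3 values is an error, a constant vector is reported as
#' degenerate with an undefined p-value rather than failing downstream.
#'
#' @param x numeric vector of at least 3 values.
#' @param alpha flag level.
#' @return a list with `statistic`, `p_value`, `normal`
#'   (`p_value >= alpha`), `degenerate`.
#' @export
shapiroScreen <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3)
    stop("at least 3 values are required for the Shapiro-Wilk test",
         call. = FALSE)
  if (stats::sd(x) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_,
                normal = NA, degenerate = TRUE))
  sw <- stats::shapiro.test(x)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       normal = sw$p.value >= alpha, degenerate = FALSE)
}

#' Long-format study table feeding the ANOVA layer
#'
#' Melts the per-bottle tables produced by the pipeline stages into one
#' long table keyed by bottle, substrate, factor levels, run and replicate,
#' with one row per (bottle, response).  Replicates from different gas runs
#' are pooled by the downstream models (the run factor is dropped, matching
#' the study designs this package emulates; a run-effect check is available
#' by passing `group = "run"` to [oneWayAnova()]).
#'
#' @param study a [FermStudy-class] object.
#' @param kinetics optional output of [fitKinetics()].
#' @param partition optional output of [gasPartition()].
#' @param nutritive optional output of [nutritiveTable()].
#' @return a long `data.frame`: `bottle_id`, `substrate`, `cut`, `part`,
#'   `run`, `replicate`, `response`, `value`.
#' @export
buildStudyTable <- function(study, kinetics = NULL, partition = NULL,
                            nutritive = NULL) {
  keep <- !isBlank(study)
  cd <- as.data.frame(colData(study)[keep, ])
  key <- cd[, c("bottle_id", "substrate", "cut", "part", "run", "replicate")]
  if (!"omcv" %in% assayNames(study)) study <- toOMCV(study)
  resp <- data.frame(key,
                     omcv_final = assay(study, "omcv")[nrow(study), keep],
                     dom_pct = domPercent(cd$incubated_om_g,
                                          cd$residue_om_g),
                     ph = cd$ph, check.names = FALSE)
  add <- function(resp, tab, cols) {
    if (is.null(tab)) return(resp)
    merge(resp, tab[, c("bottle_id", cols)], by = "bottle_id", sort = FALSE)
  }
  resp <- add(resp, kinetics, c("A", "B", "C", "tmax_h", "rmax_ml_h"))
  resp <- add(resp, partition, c("co2_mmol_g", "ch4_mmol_g", "ch4_ml_g",
                                 "ch4_pct_total_gas", "vfa_total",
                                 "bcfa_pct", "a_p_ratio"))
  resp <- add(resp, nutritive, c("me_mj_kg", "nsc_pct"))
  idcols <- c("bottle_id", "substrate", "cut", "part", "run", "replicate")
  long <- stats::reshape(
    resp, direction = "long",
    varying = setdiff(names(resp), idcols),
    v.names = "value", timevar = "response",
    times = setdiff(names(resp), idcols), idvar = "bottle_id")
  rownames(long) <- NULL
  long[order(long$response, long$substrate, long$run, long$replicate),
       c(idcols, "response", "value")]
}

# Pairwise Tukey adjusted p-values for k balanced group means.
.tukeyPairwiseP <- function(means, ms_within, df, n) {
  k <- length(means)
  if (df <= 0) stop("residual df must be > 0", call. = FALSE)
  if (length(n) > 1) n <- length(n) / sum(1 / n)  # harmonic-mean fallback
  se <- sqrt(ms_within / n)
  p <- matrix(1, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d <- abs(means[i] - means[j])
    # zero residual variance: identical means agree, distinct ones differ
    p[i, j] <- p[j, i] <- if (se == 0) as.numeric(d <= 1e-12 * max(1, d))
    else stats::ptukey(d / se, k, df, lower.tail = FALSE)
  }
  p
}

# Insert-and-absorb compact letter display from a significance matrix.
.cldFromSig <- function(sig, means) {
  k <- length(means)
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    hit <- vapply(sets, function(s) all(c(i, j) %in% s), logical(1))
    if (!any(hit)) next
    new_sets <- sets[!hit]
    for (s in sets[hit]) new_sets <- c(new_sets, list(setdiff(s, i)),
                                       list(setdiff(s, j)))
    # absorb: drop sets contained in another set
    new_sets <- new_sets[lengths(new_sets) > 0]
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(length(new_sets[[a]]) == length(new_sets[[b]]) && a < b))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  ord <- order(-vapply(sets, function(s) max(means[s]), numeric(1)),
               -lengths(sets))
  sets <- sets[ord]
  letters_out <- character(k)
  for (s in seq_along(sets))
    for (g in sets[[s]])
      letters_out[g] <- paste0(letters_out[g], letters[s])
  vapply(letters_out, function(x)
    paste(sort(strsplit(x, "")[[1]]), collapse = ""), character(1),
    USE.NAMES = FALSE)
}

#' Tukey HSD compact letter display
#'
#' Computes all pairwise Tukey-adjusted comparisons of `k` group means from
#' the within-group mean square and assigns letters by the insert-and-absorb
#' algorithm: groups sharing a letter do not differ at level `alpha`; groups
#' sharing no letter do.  Letters are ordered `a`, `b`, ... by descending
#' mean.  For unbalanced groups the harmonic mean of the `n` is used and
#' flagged in the result.
#'
#' @param means named vector of group means.
#' @param ms_within residual (within-group) mean square.
#' @param df residual degrees of freedom, > 0.
#' @param n common per-group size (or vector of sizes).
#' @param alpha significance level.
#' @return a list with `letters` (named character vector), `p_matrix`
#'   (Tukey-adjusted pairwise p-values) and `harmonic_n_used`.
#' @export
tukeyLetters <- function(means, ms_within, df, n, alpha = 0.05) {
  stopifnot(length(means) >= 2)
  if (is.null(names(means))) names(means) <- seq_along(means)
  p <- .tukeyPairwiseP(means, ms_within, df, n)
  sig <- p < alpha
  ltr <- .cldFromSig(sig, means)
  names(ltr) <- names(means)
  list(letters = ltr, p_matrix = p,
       harmonic_n_used = length(n) > 1 && stats::var(n) > 0)
}

.semPooled <- function(ms_within, n) {
  if (length(n) > 1) n <- length(n) / sum(1 / n)
  sqrt(ms_within / n)
}

#' One-way ANOVA with Tukey letters and SEM
#'
#' Fits `value ~ group` for one response of a long study table, reports the
#' group effect F-test, the pooled SEM `sqrt(MS_within / n)`, group means
#' and the Tukey HSD compact letter display at level `alpha`.
#'
#' @param table a long table from [buildStudyTable()].
#' @param response response name to analyse.
#' @param group grouping column (default `"substrate"`).
#' @param alpha significance level for the letters.
#' @return a list with `response`, `p_value`, `f_value`, `df`, `ms_within`,
#'   `sem`, `means`, `n_per_group`, `letters`, `p_matrix`, `shapiro`.
#' @export
oneWayAnova <- function(table, response, group = "substrate",
                        alpha = 0.05) {
  d <- table[table$response == response & is.finite(table$value), ]
  if (!nrow(d)) stop("no data for response ", response, call. = FALSE)
  d$g <- factor(d[[group]])
  if (nlevels(d$g) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- tapply(d$value, d$g, length)
  if (any(n < 2)) stop("need at least 2 replicates per group",
                       call. = FALSE)
  if (stats::var(d$value) == 0) {
    means <- tapply(d$value, d$g, mean)
    return(list(response = response, p_value = 1, f_value = 0,
                df = c(nlevels(d$g) - 1L, nrow(d) - nlevels(d$g)),
                ms_within = 0, sem = 0, means = means, n_per_group = n,
                letters = stats::setNames(rep("a", length(means)),
                                          names(means)),
                p_matrix = NULL, shapiro = shapiroScreen(d$value)))
  }
  fit <- stats::aov(value ~ g, data = d)
  a <- suppressWarnings(stats::anova(fit))
  means <- tapply(d$value, d$g, mean)
  tl <- tukeyLetters(means, a["Residuals", "Mean Sq"],
                     a["Residuals", "Df"], as.numeric(n), alpha)
  list(response = response,
       p_value = a["g", "Pr(>F)"], f_value = a["g", "F value"],
       df = unname(a[["Df"]]), ms_within = a["Residuals", "Mean Sq"],
       sem = .semPooled(a["Residuals", "Mean Sq"], as.numeric(n)),
       means = means, n_per_group = n,
       letters = tl$letters, p_matrix = tl$p_matrix,
       shapiro = shapiroScreen(stats::resid(fit)))
}

#' Two-way factorial ANOVA (cut x plant part) with interaction
#'
#' Fits `value ~ cut * part` for one response; reports p-values for the cut
#' main effect, the part main effect and their interaction, cell means, the
#' pooled SEM, and Tukey letters comparing the four parts within each cut
#' (using the full-model residual mean square), matching the reporting
#' convention of cut-by-part forage studies.
#'
#' @inheritParams oneWayAnova
#' @return a list with `response`, `p_cut`, `p_part`, `p_interaction`,
#'   `ms_within`, `sem`, `cell_means`, `letters_by_cut`, `shapiro`.
#' @export
twoWayAnova <- function(table, response, alpha = 0.05) {
  d <- table[table$response == response & is.finite(table$value), ]
  if (!nrow(d)) stop("no data for response ", response, call. = FALSE)
  d$cut <- factor(d$cut); d$part <- factor(d$part)
  cells <- table(d$cut, d$part)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop("empty design cell: cut ", rownames(cells)[bad[1]], " x part ",
         colnames(cells)[bad[2]], call. = FALSE)
  }
  if (stats::var(d$value) == 0) {
    cm <- tapply(d$value, list(d$cut, d$part), mean)
    lbc <- lapply(levels(d$cut), function(cl)
      stats::setNames(rep("a", ncol(cm)), colnames(cm)))
    names(lbc) <- levels(d$cut)
    return(list(response = response, p_cut = 1, p_part = 1,
                p_interaction = 1, ms_within = 0, sem = 0,
                cell_means = cm, letters_by_cut = lbc,
                shapiro = shapiroScreen(d$value)))
  }
  fit <- stats::aov(value ~ cut * part, data = d)
  a <- suppressWarnings(stats::anova(fit))
  msw <- a["Residuals", "Mean Sq"]
  dfr <- a["Residuals", "Df"]
  cell_means <- tapply(d$value, list(d$cut, d$part), mean)
  n_cell <- tapply(d$value, list(d$cut, d$part), length)
  letters_by_cut <- lapply(levels(d$cut), function(cl) {
    tukeyLetters(cell_means[cl, ], msw, dfr,
                 as.numeric(n_cell[cl, ]), alpha)$letters
  })
  names(letters_by_cut) <- levels(d$cut)
  pv <- function(term) if (term %in% rownames(a)) a[term, "Pr(>F)"] else NA
  list(response = response,
       p_cut = pv("cut"), p_part = pv("part"),
       p_interaction = pv("cut:part"),
       ms_within = msw, sem = .semPooled(msw, as.numeric(n_cell)),
       cell_means = cell_means, letters_by_cut = letters_by_cut,
       shapiro = shapiroScreen(stats::resid(fit)))
}

#' ANOVA report across all responses of a study table
#'
#' Runs [oneWayAnova()] (single-factor designs) or [twoWayAnova()]
#' (cut-by-part designs) for every response in the table and assembles the
#' group means, Tukey letters, SEM and p-values into one tidy report.
#'
#' @param table a long table from [buildStudyTable()].
#' @param design `"oneway"` or `"twoway"`; by default inferred from the
#'   presence of plant-part factor levels.
#' @param alpha significance level.
#' @param digits significant figures for the reported means
#'   ([signifHalfUp()] rounding); `NULL` for no rounding.
#' @return a `data.frame` with one row per (response, group): `response`,
#'   `group`, `mean`, `letters`, `sem`, and the model p-values.
#' @export
anovaReport <- function(table, design = NULL, alpha = 0.05, digits = 3) {
  if (is.null(design))
    design <- if (any(!is.na(table$part))) "twoway" else "oneway"
  design <- match.arg(design, c("oneway", "twoway"))
  rows <- list()
  rnd <- function(x) if (is.null(digits)) x else signifHalfUp(x, digits)
  for (resp in unique(table$response)) {
    if (design == "oneway") {
      r <- oneWayAnova(table, resp, alpha = alpha)
      rows[[resp]] <- data.frame(
        response = resp, group = names(r$means),
        mean = rnd(as.numeric(r$means)),
        letters = unname(r$letters), sem = r$sem, p_value = r$p_value,
        shapiro_p = r$shapiro$p_value, stringsAsFactors = FALSE)
    } else {
      r <- twoWayAnova(table, resp, alpha = alpha)
      cm <- r$cell_means
      grid <- expand.grid(cut = rownames(cm), part = colnames(cm),
                          stringsAsFactors = FALSE)
      rows[[resp]] <- data.frame(
        response = resp,
        group = paste(grid$cut, grid$part, sep = ":"),
        mean = rnd(cm[cbind(grid$cut, grid$part)]),
        letters = vapply(seq_len(nrow(grid)), function(i)
          unname(r$letters_by_cut[[grid$cut[i]]][grid$part[i]]),
          character(1)),
        sem = r$sem, p_cut = r$p_cut, p_part = r$p_part,
        p_interaction = r$p_interaction,
        shapiro_p = r$shapiro$p_value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
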