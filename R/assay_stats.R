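#' Decision thresholds for the three validation assays
#'
#' Defaults are the thresholds used throughout the screen-and-validate
#' workflow: expression screen P < 0.05 with fold change > 1.3 against the
#' negative control; pull-down log2 enrichment > 0.5 with P < 0.05;
#' luciferase repression at P < 0.01; seed-mutant abrogation judged at
#' alpha 0.05. All fold-change cutoffs are strict inequalities.
#'
#' @param screen_fc_min Minimum linear fold change for the screen (strict).
#' @param screen_alpha Significance level for the screen t-test.
#' @param pulldown_log2fc_min Minimum log2 enrichment for the pull-down
#'   (strict).
#' @param pulldown_alpha Significance level for the pull-down t-test.
#' @param luciferase_alpha Significance level for reporter repression.
#' @param mutant_rescue_alpha Significance level for the seed-mutant
#'   abrogation decision.
#' @return A list of class `"thresholds"`.
#' @export
default_thresholds <- function(screen_fc_min = 1.3, screen_alpha = 0.05,
                               pulldown_log2fc_min = 0.5, pulldown_alpha = 0.05,
                               luciferase_alpha = 0.01,
                               mutant_rescue_alpha = 0.05) {
  thr <- list(screen_fc_min = screen_fc_min, screen_alpha = screen_alpha,
              pulldown_log2fc_min = pulldown_log2fc_min,
              pulldown_alpha = pulldown_alpha,
              luciferase_alpha = luciferase_alpha,
              mutant_rescue_alpha = mutant_rescue_alpha)
  alphas <- c(screen_alpha, pulldown_alpha, luciferase_alpha, mutant_rescue_alpha)
  if (any(alphas <= 0 | alphas >= 1)) {
    stop("all significance levels must lie in (0, 1)", call. = FALSE)
  }
  if (screen_fc_min <= 0 || pulldown_log2fc_min < 0) {
    stop("fold-change thresholds must be positive", call. = FALSE)
  }
  class(thr) <- "thresholds"
  thr
}

#' Two-sample equal-variance (Student) t-test
#'
#' Pooled-variance two-tailed t-test, the test applied to every replicate
#' comparison in the pipeline. Degenerate zero-variance input is handled by
#' convention: identical means give t = 0, p = 1; different means with zero
#' pooled variance give p = 0.
#'
#' @param x,y Numeric replicate vectors (each of length >= 2).
#' @return List with `statistic` (t), `df`, and `p_value` (two-tailed).
#' @examples
#' two_sample_ttest(c(1, 2, 3), c(2, 3, 4))
#' @export
two_sample_ttest <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample must contain at least 2 replicates", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("replicate values contain NA", call. = FALSE)
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2L)
  df <- length(x) + length(y) - 2L
  if (pooled_var == 0) {
    if (mean(x) == mean(y)) {
      return(list(statistic = 0, df = df, p_value = 1))
    }
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, df = df, p_value = 0))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Relative quantification by the delta-delta-Ct method
#'
#' Per replicate, delta-Ct = Ct(target) - Ct(reference); the linear fold
#' change is `2^-(mean dCt_treated - mean dCt_control)` and the p-value is a
#' two-sample equal-variance t-test on the per-replicate delta-Ct values.
#'
#' @param treated,control Data frames with one row per replicate and numeric
#'   columns `ct_target` and `ct_reference`.
#' @param gene,species,assay Optional identifiers carried into the result.
#' @return A list of class `"fold_change_result"`: `gene`, `species`,
#'   `assay`, `linear_fc`, `log2_fc`, `p_value`, `n_treated`, `n_control`.
#' @export
ddct_fold_change <- function(treated, control, gene = NA_character_,
                             species = NA_character_, assay = NA_character_) {
  for (nm in c("ct_target", "ct_reference")) {
    if (!nm %in% names(treated) || !nm %in% names(control)) {
      stop("Ct tables must carry column '", nm, "'", call. = FALSE)
    }
  }
  if (anyNA(treated$ct_reference) || anyNA(control$ct_reference)) {
    stop("missing reference Ct value", call. = FALSE)
  }
  dct_t <- treated$ct_target - treated$ct_reference
  dct_c <- control$ct_target - control$ct_reference
  ddct <- mean(dct_t) - mean(dct_c)
  tt <- two_sample_ttest(dct_t, dct_c)
  structure(
    list(gene = gene, species = species, assay = assay,
         linear_fc = 2^(-ddct), log2_fc = -ddct, p_value = tt$p_value,
         n_treated = length(dct_t), n_control = length(dct_c)),
    class = "fold_change_result"
  )
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> %s/%s [%s]: FC = %.3f (log2 %.3f), p = %.4g, n = %d/%d\n",
              x$gene, x$species, x$assay, x$linear_fc, x$log2_fc, x$p_value,
              x$n_treated, x$n_control))
  invisible(x)
}

new_assay_call <- function(gene, species, assay, direction, passed, stats) {
  structure(
    list(gene = gene, species = species, assay = assay,
         direction = direction, passed = isTRUE(passed), stats = stats),
    class = "assay_call"
  )
}

#' @export
print.assay_call <- function(x, ...) {
  cat(sprintf("<assay_call> %s/%s %s (%s): %s\n", x$gene, x$species, x$assay,
              x$direction, if (x$passed) "PASS" else "fail"))
  invisible(x)
}

#' Expression-screen call for one perturbation mode
#'
#' A loss-of-function (LOF) comparison passes on derepression: linear fold
#' change >= `screen_fc_min` (strictly greater than on the repression scale,
#' applied symmetrically) and p < `screen_alpha`. Gain-of-function (GOF) and
#' morpholino-rescue comparisons pass on repression: linear fold change
#' <= `1/screen_fc_min` and p < `screen_alpha`. A fold change exactly at the
#' cutoff fails (strict inequality).
#'
#' @param fc A [ddct_fold_change()] result computed against the mode's
#'   control condition.
#' @param mode `"GOF"`, `"LOF"`, or `"rescue"`.
#' @param thresholds A [default_thresholds()] object.
#' @return An `"assay_call"`.
#' @export
screen_call <- function(fc, mode = c("GOF", "LOF", "rescue"),
                        thresholds = default_thresholds()) {
  mode <- match.arg(mode)
  stopifnot(inherits(fc, "fold_change_result"))
  sig <- fc$p_value < thresholds$screen_alpha
  if (mode == "LOF") {
    passed <- sig && fc$linear_fc > thresholds$screen_fc_min
    direction <- "derepressed"
  } else {
    passed <- sig && fc$linear_fc < 1 / thresholds$screen_fc_min
    direction <- "repressed"
  }
  new_assay_call(fc$gene, fc$species, "screen", direction, passed, fc)
}

#' Gene-level screen outcome
#'
#' A gene passes the screen if it passes in either the gain-of-function or
#' the loss-of-function arm.
#'
#' @param gof_call,lof_call `"assay_call"` objects from [screen_call()];
#'   either may be `NULL` if that arm was not run.
#' @return An `"assay_call"` with assay `"screen"`.
#' @export
screen_gene_call <- function(gof_call, lof_call) {
  calls <- Filter(Negate(is.null), list(gof_call, lof_call))
  if (length(calls) == 0L) stop("at least one screen arm is required", call. = FALSE)
  passed <- any(vapply(calls, function(cl) cl$passed, logical(1)))
  first <- calls[[1L]]
  dirs <- vapply(calls, function(cl) if (cl$passed) cl$direction else NA_character_,
                 character(1))
  direction <- if (passed) stats::na.omit(dirs)[1L] else first$direction
  new_assay_call(first$gene, first$species, "screen", direction, passed,
                 lapply(calls, `[[`, "stats"))
}

#' Pull-down enrichment call
#'
#' Log2 enrichment is the reference-normalized abundance ratio between the
#' biotinylated-miRNA bait and a control-miRNA bait (delta-delta-Ct on the
#' bait/control Ct tables). Passes iff log2 enrichment > the cutoff
#' (strictly) and p < alpha.
#'
#' @param bait_rows,control_bait_rows Replicate Ct tables (columns
#'   `ct_target`, `ct_reference`) for the miRNA bait and the control bait.
#' @inheritParams ddct_fold_change
#' @param thresholds A [default_thresholds()] object.
#' @return An `"assay_call"` with assay `"pulldown"`.
#' @export
pulldown_enrichment_call <- function(bait_rows, control_bait_rows,
                                     gene = NA_character_,
                                     species = NA_character_,
                                     thresholds = default_thresholds()) {
  if (is.null(control_bait_rows) || nrow(control_bait_rows) == 0L) {
    stop("control bait measurements are missing", call. = FALSE)
  }
  fc <- ddct_fold_change(bait_rows, control_bait_rows, gene = gene,
                         species = species, assay = "pulldown")
  passed <- fc$log2_fc > thresholds$pulldown_log2fc_min &&
    fc$p_value < thresholds$pulldown_alpha
  new_assay_call(gene, species, "pulldown", "enriched", passed, fc)
}

#' Dual-luciferase percent activity
#'
#' Per well, the construct signal (Renilla) is normalized to the
#' co-transfected transfection control (firefly); percent activity is the
#' mean normalized treatment signal over the mean normalized control signal,
#' times 100 (scrambled-duplex control = 100%). The p-value is a two-sample
#' equal-variance t-test on the per-well normalized values.
#'
#' @param treatment_wells,control_wells Data frames with numeric columns
#'   `renilla` and `firefly` (one row per well); firefly must be positive.
#' @param construct Optional construct identifier carried into the result.
#' @return List of class `"luciferase_result"`: `construct`, `percent`,
#'   `p_value`, `n_treatment`, `n_control`, and the per-well normalized
#'   values (`norm_treatment`, `norm_control`).
#' @export
luciferase_percent_activity <- function(treatment_wells, control_wells,
                                        construct = NA_character_) {
  for (d in list(treatment_wells, control_wells)) {
    if (!all(c("renilla", "firefly") %in% names(d))) {
      stop("well tables must carry columns 'renilla' and 'firefly'", call. = FALSE)
    }
    if (any(d$firefly <= 0)) {
      stop("nonpositive firefly reading; cannot normalize", call. = FALSE)
    }
  }
  nt <- treatment_wells$renilla / treatment_wells$firefly
  nc <- control_wells$renilla / control_wells$firefly
  tt <- two_sample_ttest(nt, nc)
  structure(
    list(construct = construct, percent = 100 * mean(nt) / mean(nc),
         p_value = tt$p_value, n_treatment = length(nt), n_control = length(nc),
         norm_treatment = nt, norm_control = nc),
    class = "luciferase_result"
  )
}

#' @export
print.luciferase_result <- function(x, ...) {
  cat(sprintf("<luciferase_result> %s: %.1f%% activity, p = %.4g (n = %d/%d)\n",
              x$construct, x$percent, x$p_value, x$n_treatment, x$n_control))
  invisible(x)
}

#' Luciferase repression call
#'
#' Passes iff percent activity < 100 and p < the luciferase alpha.
#'
#' @param percent_result A [luciferase_percent_activity()] result.
#' @param gene,species Optional identifiers.
#' @param thresholds A [default_thresholds()] object.
#' @return An `"assay_call"` with assay `"luciferase"`.
#' @export
luciferase_repression_call <- function(percent_result, gene = NA_character_,
                                       species = NA_character_,
                                       thresholds = default_thresholds()) {
  stopifnot(inherits(percent_result, "luciferase_result"))
  passed <- percent_result$percent < 100 &&
    percent_result$p_value < thresholds$luciferase_alpha
  new_assay_call(gene, species, "luciferase", "repressed", passed, percent_result)
}

#' Seed-mutant abrogation test
#'
#' Given a wild-type reporter that passed repression, decides whether point
#' mutations in the seed-binding sequence abrogated the repression. The
#' default reading (`"not_repressed"`) calls abrogation when the mutant
#' construct shows no significant repression at `mutant_rescue_alpha`. The
#' alternative reading (`"exceeds_wildtype"`) calls abrogation when the
#' mutant's normalized activity significantly exceeds the wild-type's
#' (one comparison on the per-well normalized values).
#'
#' @param wildtype_call The wild-type `"assay_call"` (must have passed).
#' @param mutant_percent_result [luciferase_percent_activity()] result for
#'   the mutant construct.
#' @param thresholds A [default_thresholds()] object.
#' @param method `"not_repressed"` (default) or `"exceeds_wildtype"`.
#' @return List with `abrogated` flag and the comparison `p_value`.
#' @export
seed_mutant_rescue_test <- function(wildtype_call, mutant_percent_result,
                                    thresholds = default_thresholds(),
                                    method = c("not_repressed",
                                               "exceeds_wildtype")) {
  method <- match.arg(method)
  stopifnot(inherits(wildtype_call, "assay_call"),
            inherits(mutant_percent_result, "luciferase_result"))
  if (!wildtype_call$passed) {
    stop("abrogation is only defined for a wild-type construct that passed repression",
         call. = FALSE)
  }
  alpha <- thresholds$mutant_rescue_alpha
  if (method == "not_repressed") {
    repressed <- mutant_percent_result$percent < 100 &&
      mutant_percent_result$p_value < alpha
    return(list(abrogated = !repressed, p_value = mutant_percent_result$p_value))
  }
  wt <- wildtype_call$stats
  if (!inherits(wt, "luciferase_result")) {
    stop("wild-type call does not carry per-well luciferase values", call. = FALSE)
  }
  tt <- two_sample_ttest(mutant_percent_result$norm_treatment, wt$norm_treatment)
  abrogated <- mean(mutant_percent_result$norm_treatment) > mean(wt$norm_treatment) &&
    tt$p_value < alpha
  list(abrogated = abrogated, p_value = tt$p_value)
}

#' Flatten assay-call objects into a calls table
#'
#' @param calls List of `"assay_call"` objects.
#' @return Data frame with columns `species`, `symbol`, `assay`, `result`
#'   (`"pass"`/`"fail"`), suitable for [build_evidence_matrix()].
#' @export
as_call_table <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(species = character(), symbol = character(),
                      assay = character(), result = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(species = cl$species, symbol = cl$gene, assay = cl$assay,
               result = if (cl$passed) "pass" else "fail",
               stringsAsFactors = FALSE)
  }))
}
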