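#' Sequential classify-then-quantify screening
#'
#' Runs the screening workflow of the published models over a batch of
#' compounds: each structure is curated implicitly (descriptor computation
#' fails on unusable structures, and failures are logged rather than
#' aborting the batch), classified as active (`A`) or weak/not active (`I`),
#' and - when classified active with a reliable prediction - its T4-hTTR
#' competing potency (Log RP) is predicted. Compounds with a reliable
#' Log RP at or above the strong-binder threshold are flagged as strong
#' hTTR binders.
#'
#' Reliability follows the applicability-domain framework: a classification
#' is unreliable when it falls outside the structural domain (when `lda_ad`
#' is supplied), when the posterior falls inside the uncertain band, or when
#' its entropy exceeds the training maximum; a regression prediction is
#' unreliable outside the leverage cutoff, outside the training response
#' range, or with a prediction interval wider than the training maximum
#' (when `mlr_fit`/`mlr_ad` are supplied).
#'
#' @param compounds Data frame with columns `id` and `smiles`, or a
#'   character vector of SMILES.
#' @param classifier Classification model (default [frozen_lda()]).
#' @param regressor Potency model (default [frozen_mlr()]).
#' @param lda_ad Optional [fit_classification_ad()] domain for the
#'   classifier.
#' @param mlr_fit,mlr_ad Optional [qsar_mlr()] fit and
#'   [fit_regression_ad()] domain backing the regression reliability
#'   checks.
#' @param strong_threshold Strong-binder threshold on Log RP (default taken
#'   from `regressor`).
#' @param post_threshold Posterior reliability threshold (default 0.75).
#' @return An object of class `screening_result`: a list with `results`
#'   (one row per screened compound: descriptors, class, posterior, AD
#'   flags, Log RP, tier), `failures` (id + error message), and `summary`
#'   (per-tier counts and percentages).
#' @export
sequential_screen <- function(compounds,
                              classifier = frozen_lda(),
                              regressor = frozen_mlr(),
                              lda_ad = NULL, mlr_fit = NULL, mlr_ad = NULL,
                              strong_threshold = NULL,
                              post_threshold = 0.75) {
  if (is.character(compounds)) {
    compounds <- data.frame(id = if (!is.null(names(compounds)))
      names(compounds) else paste0("cmpd", seq_along(compounds)),
      smiles = compounds, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "smiles") %in% names(compounds)))
  if (is.null(strong_threshold)) {
    strong_threshold <- regressor$strong_threshold %||% -1.26
  }
  rows <- list(); fails <- list()
  for (k in seq_len(nrow(compounds))) {
    id <- compounds$id[[k]]; smi <- compounds$smiles[[k]]
    res <- tryCatch({
      desc <- compute_model_descriptors(smi)
      cl <- frozen_classify(desc[classifier$descriptors], model = classifier)
      post_a <- cl$posterior[["A"]]
      ent <- shannon_entropy(cl$posterior)
      if (!is.null(lda_ad)) {
        cv <- assess_classification(desc[classifier$descriptors], classifier,
                                    lda_ad, post_threshold)
        struct_flag <- cv$structural
        cls_reliable <- cv$overall == "reliable"
      } else {
        struct_flag <- NA_character_
        cls_reliable <- max(cl$posterior) >= post_threshold
      }
      logrp <- NA_real_; lev <- NA_real_; pi_w <- NA_real_
      reg_reliable <- NA
      tier <- NA_character_
      if (!cls_reliable) {
        tier <- "unreliable"
      } else if (cl$class == "I") {
        tier <- "weak/not active"
      } else {
        logrp <- frozen_predict_logrp(desc[regressor$descriptors],
                                      model = regressor)
        if (!is.null(mlr_fit) && !is.null(mlr_ad)) {
          rv <- assess_regression(desc[mlr_fit$descriptors], mlr_fit, mlr_ad)
          lev <- rv$leverage; pi_w <- rv$pi_width
          reg_reliable <- rv$overall == "reliable"
        } else {
          reg_reliable <- TRUE
        }
        if (!reg_reliable) {
          tier <- "unreliable"
          logrp <- NA_real_  # Log RP reported only for reliable actives
        } else {
          tier <- if (logrp >= strong_threshold) "active-strong"
                  else "active-moderate"
        }
      }
      data.frame(id = id, smiles = smi,
                 GATS3e = desc[["GATS3e"]], ATSC6p = desc[["ATSC6p"]],
                 GATS8m = desc[["GATS8m"]], MIC2 = desc[["MIC2"]],
                 piPC5 = desc[["piPC5"]], GGI9 = desc[["GGI9"]],
                 AATSC0e = desc[["AATSC0e"]],
                 class = cl$class, posterior_A = post_a, entropy = ent,
                 structural_ad = struct_flag, log_rp = logrp,
                 leverage = lev, pi_width = pi_w,
                 strong_binder = !is.na(logrp) && logrp >= strong_threshold,
                 tier = tier, stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        id = id, smiles = smi, error = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  results <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  failures <- if (length(fails) > 0) do.call(rbind, fails) else NULL
  summary <- NULL
  if (!is.null(results)) {
    tiers <- table(factor(results$tier,
                          levels = c("weak/not active", "active-moderate",
                                     "active-strong", "unreliable")))
    n_rel <- sum(results$tier != "unreliable")
    n_act <- sum(results$tier %in% c("active-moderate", "active-strong"))
    summary <- list(
      screened = nrow(results),
      failed = nrow(compounds) - nrow(results),
      tiers = as.list(tiers),
      reliable_pct = 100 * n_rel / nrow(results),
      active_pct = if (n_rel > 0) 100 * n_act / n_rel else NA_real_,
      strong_pct = if (n_act > 0)
        100 * sum(results$tier == "active-strong") / n_act else NA_real_)
  }
  structure(list(results = results, failures = failures, summary = summary),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  s <- x$summary
  if (is.null(s)) { cat("Screening produced no results\n"); return(invisible(x)) }
  cat("Sequential screening:", s$screened, "compounds screened,",
      s$failed, "failed\n")
  for (t in names(s$tiers)) cat(sprintf("  %-16s %d\n", t, s$tiers[[t]]))
  cat(sprintf("  reliable: %.1f%%  active (of reliable): %.1f%%  strong (of active): %.1f%%\n",
              s$reliable_pct, s$active_pct, s$strong_pct))
  invisible(x)
}

#' Write a screening result to disk
#'
#' @param screen A [sequential_screen()] result.
#' @param csv_path Per-compound CSV output.
#' @param summary_path Optional JSON path for the category summary.
#' @return Invisibly, the results data frame.
#' @export
write_screening <- function(screen, csv_path, summary_path = NULL) {
  utils::write.csv(screen$results, csv_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(screen$summary, summary_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(screen$results)
}
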