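#' Read a compound table
#'
#' Reads a CSV of compounds with columns `id`, optional `casrn`, `smiles`,
#' and the optional endpoint columns `median_activity` and `ec50_um`
#' (semicolon-separated when a compound has replicate values). A plain SMILES
#' file (one SMILES per line, optional whitespace-separated id) is also
#' accepted.
#'
#' @param path Path to a CSV or plain SMILES file.
#' @param format `"csv"` or `"smi"`; guessed from the file extension by
#'   default.
#' @return A data frame with columns `id`, `casrn`, `smiles`,
#'   `median_activity` (list column of numeric vectors), `ec50_um` (list
#'   column of numeric vectors).
#' @export
read_compound_table <- function(path, format = c("auto", "csv", "smi")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(smi|smiles|txt)$", path, ignore.case = TRUE)) "smi" else "csv"
  }
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smiles <- vapply(parts, `[[`, character(1), 1L)
    id <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else p[[1]], character(1))
    return(data.frame(id = id, casrn = NA_character_, smiles = smiles,
                      median_activity = I(rep(list(numeric(0)), length(id))),
                      ec50_um = I(rep(list(numeric(0)), length(id))),
                      stringsAsFactors = FALSE))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "smiles") %in% names(raw))) {
    stop("compound CSV must have at least columns 'id' and 'smiles'")
  }
  split_num <- function(x) {
    lapply(x, function(v) {
      if (is.null(v) || is.na(v) || !nzchar(trimws(v))) return(numeric(0))
      as.numeric(strsplit(v, ";", fixed = TRUE)[[1]])
    })
  }
  data.frame(
    id = raw$id,
    casrn = if ("casrn" %in% names(raw)) raw$casrn else NA_character_,
    smiles = raw$smiles,
    median_activity = I(split_num(if ("median_activity" %in% names(raw))
      raw$median_activity else rep(NA_character_, nrow(raw)))),
    ec50_um = I(split_num(if ("ec50_um" %in% names(raw))
      raw$ec50_um else rep(NA_character_, nrow(raw)))),
    stringsAsFactors = FALSE
  )
}

# TRUE when the SMILES contains a bracket atom carrying a formal charge.
.has_charged_atom <- function(smiles) {
  grepl("\\[[^][]*[+-][^][]*\\]", smiles)
}

# element symbols appearing in a SMILES via the parsed graph
.graph_elements <- function(smiles) {
  g <- tryCatch(build_graph(smiles, explicit_h = FALSE), error = function(e) NULL)
  if (is.null(g)) return(NULL)
  unique(g$atoms$element)
}

#' Curate a compound table
#'
#' Applies the structure-curation rules used before modelling and screening:
#' multi-component notations (dot-disconnected salts and mixtures), compounds
#' containing elements outside the organic subset (organometals/inorganics),
#' charged species, records without a usable structure, and duplicates are
#' excluded. Stereoisomers are reduced to their non-chiral form before
#' duplicate detection (configurable), so stereoisomer pairs collapse to one
#' record.
#'
#' @param records Data frame as returned by [read_compound_table()], or any
#'   data frame with `id` and `smiles` columns.
#' @param strip_stereo Treat stereoisomers as duplicates of their non-chiral
#'   form (default `TRUE`).
#' @return A list with `kept` (curated data frame, with an added
#'   `canonical_smiles` column) and `report` (data frame `id`, `reason` for
#'   every exclusion; reasons are `salt`, `mixture`, `organometal`, `charged`,
#'   `ambiguous_identifier`, `duplicate`, `no_structure`).
#' @examples
#' recs <- data.frame(id = c("a", "b"),
#'                    smiles = c("OC(=O)C(F)(F)F", "CC(=O)[O-].[Na+]"))
#' cur <- curate(recs)
#' cur$report
#' @export
curate <- function(records, strip_stereo = TRUE) {
  stopifnot(all(c("id", "smiles") %in% names(records)))
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  canon <- rep(NA_character_, n)
  for (k in seq_len(n)) {
    s <- records$smiles[[k]]
    if (is.na(s) || !nzchar(trimws(s))) {
      has_cas <- "casrn" %in% names(records) && !is.na(records$casrn[[k]]) &&
        nzchar(records$casrn[[k]])
      reason[k] <- if (has_cas) "ambiguous_identifier" else "no_structure"
      next
    }
    cs <- tryCatch(canonicalize_smiles(s, strip_stereo = strip_stereo,
                                       ids = records$id[[k]]),
                   error = function(e) NA_character_)
    if (is.na(cs)) { reason[k] <- "no_structure"; next }
    canon[k] <- cs
    if (grepl(".", cs, fixed = TRUE)) {
      # dot-disconnected: ionic or metal-containing components are salts,
      # otherwise a (covalent) mixture
      comps <- strsplit(cs, ".", fixed = TRUE)[[1]]
      ionic <- any(vapply(comps, .has_charged_atom, logical(1)))
      metal <- FALSE
      for (cc in comps) {
        el <- .graph_elements(cc)
        if (!is.null(el) && length(setdiff(el, .organic_elements)) > 0) metal <- TRUE
      }
      reason[k] <- if (ionic || metal) "salt" else "mixture"
      next
    }
    el <- .graph_elements(cs)
    if (is.null(el)) { reason[k] <- "no_structure"; next }
    if (length(setdiff(el, .organic_elements)) > 0) { reason[k] <- "organometal"; next }
    if (.has_charged_atom(cs)) { reason[k] <- "charged"; next }
  }
  # duplicate pass on the survivors, keep the first occurrence in input order
  ok <- which(is.na(reason))
  dup <- ok[duplicated(canon[ok])]
  reason[dup] <- "duplicate"
  kept_idx <- which(is.na(reason))
  kept <- records[kept_idx, , drop = FALSE]
  kept$canonical_smiles <- canon[kept_idx]
  rownames(kept) <- NULL
  report <- data.frame(id = records$id[!is.na(reason)],
                       reason = reason[!is.na(reason)],
                       stringsAsFactors = FALSE)
  list(kept = kept, report = report)
}

#' Assign an activity class from median-activity values
#'
#' A compound is active (class `"A"`) when its median activity in the
#' competitive binding assay is at least 50%, and weak/not active (class
#' `"I"`) otherwise. Replicate values must agree on the classification;
#' replicates straddling the 50% boundary raise an error.
#'
#' @param median_activity Numeric vector of median-activity percentages in
#'   \[0, 100\] (one or more replicate values for the same compound).
#' @return `"A"` or `"I"`.
#' @examples
#' assign_activity_class(c(93.5, 93.4))  # "A"
#' assign_activity_class(c(14.1, 10.2))  # "I"
#' @export
assign_activity_class <- function(median_activity) {
  v <- median_activity[!is.na(median_activity)]
  if (length(v) == 0) stop("no median-activity value supplied")
  if (any(v < 0 | v > 100)) stop("median activity must lie in [0, 100]")
  cls <- ifelse(v >= 50, "A", "I")
  if (length(unique(cls)) > 1) {
    stop("replicate median-activity values straddle the 50% boundary: ",
         paste(v, collapse = ", "))
  }
  cls[[1]]
}

#' Compute the Log RP endpoint
#'
#' The relative competitive potency RP of a compound is the ratio between
#' the binding affinity of the natural ligand T4 and the binding affinity of
#' the compound, both expressed as half-maximal effect concentrations (EC50,
#' in micromolar). When replicate EC50 values exist, the arithmetic mean of
#' the individual RP values is taken before the log10 transform. A compound
#' more potent than T4 (smaller EC50) has Log RP > 0.
#'
#' @param t4_ec50 EC50 of T4 (micromolar), a single positive number.
#' @param pfas_ec50 Numeric vector of EC50 values for the compound
#'   (micromolar), all positive.
#' @return log10 of the mean relative potency.
#' @examples
#' compute_log_rp(0.3, 0.03)  # tenfold stronger binder than T4: 1
#' @export
compute_log_rp <- function(t4_ec50, pfas_ec50) {
  if (!is.numeric(t4_ec50) || length(t4_ec50) != 1 || t4_ec50 <= 0) {
    stop("t4_ec50 must be a single positive concentration")
  }
  v <- pfas_ec50[!is.na(pfas_ec50)]
  if (length(v) == 0 || any(v <= 0)) {
    stop("pfas_ec50 must contain positive concentrations")
  }
  log10(mean(t4_ec50 / v))
}

#' Write a curation result to disk
#'
#' @param curated Result of [curate()].
#' @param csv_path Output CSV for the kept compounds.
#' @param report_path Optional JSON path for the exclusion report.
#' @return Invisibly, the kept data frame.
#' @export
write_curated <- function(curated, csv_path, report_path = NULL) {
  flat <- curated$kept
  for (col in c("median_activity", "ec50_um")) {
    if (col %in% names(flat) && is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]],
                            function(v) paste(v, collapse = ";"), character(1))
    }
  }
  utils::write.csv(flat, csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      list(kept = curated$kept$id,
           excluded = curated$report),
      report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(curated$kept)
}
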