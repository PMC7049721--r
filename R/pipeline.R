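#' Run the full inference pipeline
#'
#' Orchestrates the stages end-to-end: read filtering, miRNA candidate
#' selection, degradome mapping and peak categorization, permissive target
#' prediction, position profiling, criteria inference, and (when a
#' validated set is supplied) the retain-rate sweep and evaluation. All
#' effective parameters are written to a run log; re-running with identical
#' inputs and config is bit-identical apart from the timestamp line.
#'
#' @param srna,degradome paths to sRNA / degradome read files, or
#'   [read_set()] objects.
#' @param transcriptome path to a transcriptome FASTA, or a named character
#'   vector.
#' @param mirnas path to a known-miRNA FASTA, or a data frame as from
#'   [read_mirnas()].
#' @param out output directory.
#' @param genome optional genome FASTA path (or character vector) enabling
#'   the genome-matching read filter.
#' @param validated optional validated-interaction table (path or data
#'   frame).
#' @param retain_rate retain-rate for criteria inference (default 0.85).
#' @param min_peak_abund,min_mirna_abund abundance floors (default 5).
#' @param confidence peak classes used for inference: `"HC"` (default),
#'   `"LC"` or `"both"`.
#' @param permissive permissive first-pass criteria.
#' @param mfe_backend MFE backend, `"nn"` or `"vienna"`.
#' @param filters logical; apply the ambiguous-base and low-complexity
#'   read filters.
#' @param user_mirnas optional user-supplied miRNA sequences admitted
#'   without a homology match.
#' @return invisibly, a list with the intermediate and final objects
#'   (`candidates`, `peaks`, `duplexes`, `profile`, `criteria`, `sweep`,
#'   `evaluation`) and the paths written.
#' @export
run_pipeline <- function(srna, degradome, transcriptome, mirnas, out,
                         genome = NULL, validated = NULL,
                         retain_rate = 0.85, min_peak_abund = 5L,
                         min_mirna_abund = 5L,
                         confidence = c("HC", "LC", "both"),
                         permissive = permissive_criteria(),
                         mfe_backend = "nn", filters = TRUE,
                         user_mirnas = NULL) {
  confidence <- match.arg(confidence)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  rs_srna <- if (inherits(srna, "read_set")) srna else
    read_sequences(srna, kind = "sRNA")
  rs_deg <- if (inherits(degradome, "read_set")) degradome else
    read_sequences(degradome, kind = "degradome")
  tx <- if (is.character(transcriptome) && length(transcriptome) == 1L &&
            file.exists(transcriptome)) read_transcriptome(transcriptome)
    else transcriptome
  known <- if (is.data.frame(mirnas)) mirnas else read_mirnas(mirnas)
  gen <- if (is.null(genome)) NULL else if (length(genome) == 1L &&
    file.exists(genome)) read_transcriptome(genome) else genome
  val <- if (is.null(validated)) NULL else if (is.data.frame(validated))
    validated else read_validated(validated)

  if (filters || !is.null(gen)) {
    rs_srna <- preprocess_reads(rs_srna, genome = gen, ambiguous = filters,
                                complexity = filters)
    rs_deg <- preprocess_reads(rs_deg, genome = gen, ambiguous = filters,
                               complexity = filters)
  }

  candidates <- select_candidates(rs_srna, known,
                                  min_abund = min_mirna_abund,
                                  user_supplied = user_mirnas)
  profiles <- map_degradome(rs_deg, tx)
  peaks <- confident_peaks(categorize_peaks(profiles),
                           min_abund = min_peak_abund)
  used <- switch(confidence, HC = peaks[peaks$confidence == "HC", ],
                 LC = peaks[peaks$confidence == "LC", ], both = peaks)

  duplexes <- find_targets(candidates, tx, used, criteria = permissive,
                           mfe_backend = mfe_backend)
  write_interactions(duplexes, file.path(out, "interactions.tsv"))

  result <- list(candidates = candidates, peaks = peaks, duplexes = duplexes,
                 profile = NULL, criteria = NULL, sweep = NULL,
                 evaluation = NULL, out = out)
  if (!nrow(duplexes)) {
    warning("no duplexes pass the permissive criteria; ",
            "criteria inference skipped")
  } else {
    result$profile <- position_profile(duplexes,
                                       n_positions = max(nchar(duplexes$mirna_seq)))
    utils::write.table(result$profile, file.path(out, "position_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    result$criteria <- infer_criteria(duplexes, retain_rate)
    write_criteria(result$criteria, file.path(out, "criteria.txt"))
    if (!is.null(val)) {
      result$sweep <- retain_sweep(duplexes, val)
      utils::write.table(result$sweep, file.path(out, "retain_sweep.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      keep <- vapply(seq_len(nrow(duplexes)), function(i)
        passes_criteria(duplexes$states[i], duplexes$score[i],
                        duplexes$mfe_ratio[i], result$criteria), logical(1))
      result$evaluation <- evaluate_predictions(duplexes[keep, ], val)
    }
  }

  log_lines <- c(
    paste0("# parecrit ", as.character(utils::packageVersion("parecrit"))),
    paste0("# ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("retain_rate=%s", retain_rate),
    sprintf("min_peak_abund=%d", min_peak_abund),
    sprintf("min_mirna_abund=%d", min_mirna_abund),
    sprintf("confidence=%s", confidence),
    sprintf("mfe_backend=%s", mfe_backend),
    sprintf("filters=%s", filters),
    sprintf("genome_filter=%s", !is.null(gen)),
    sprintf("n_candidates=%d", nrow(candidates)),
    sprintf("n_confident_peaks=%d", nrow(used)),
    sprintf("n_duplexes=%d", nrow(duplexes))
  )
  writeLines(log_lines, file.path(out, "run_log.txt"))
  invisible(result)
}
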