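#' Configuration for the synthetic fixture generator
#'
#' The defaults describe a small but realistic paired sRNA/degradome
#' experiment: 21-nt miRNAs, transcripts of 500-1500 nt, planted cleavage
#' peaks well above the 5-read confidence floor, and optional background
#' degradation with abundances 1 + Geometric(p) (most background positions
#' carry 1-2 reads, mimicking random degradation noise).
#'
#' @param n_transcripts,transcript_len transcript count and length range.
#' @param n_mirnas,mirna_len miRNA count and length.
#' @param n_interactions number of planted miRNA-mRNA interactions (at most
#'   one per transcript; requires `n_transcripts >= n_interactions`).
#' @param peak_abundance range of planted degradome peak abundances.
#' @param background_rate per-nucleotide probability of a background
#'   degradome read (0 = clean fixture).
#' @param background_geom_p geometric parameter for background abundances.
#' @param srna_abundance range of planted miRNA abundances in the sRNA
#'   sample.
#' @param n_background_srna random non-miRNA sRNA reads (abundance 1-4,
#'   below the default candidate threshold).
#' @param interactions optional explicit plan list; each element is a list
#'   with `mirna` (index), `mm_pos`, `gu_pos`, `gap_pos` (miRNA positions)
#'   and `peak_abundance`. When `NULL`, plans are drawn inside the default
#'   permissive bounds.
#' @param two_subsets when `TRUE`, half the miRNAs follow a
#'   "conserved-like" plan (few edits, 3' biased) and half a
#'   "specific-like" plan (more 5'-end flexibility), with clade metadata to
#'   match, to exercise subset-portability analyses.
#' @return config list.
#' @export
fixture_config <- function(n_transcripts = 30L, transcript_len = c(500L, 1500L),
                           n_mirnas = 20L, mirna_len = 21L,
                           n_interactions = 20L,
                           peak_abundance = c(10L, 80L),
                           background_rate = 0,
                           background_geom_p = 0.5,
                           srna_abundance = c(20L, 200L),
                           n_background_srna = 50L,
                           interactions = NULL,
                           two_subsets = FALSE) {
  as.list(environment())
}

#' Generate a synthetic paired sRNA/degradome fixture
#'
#' Builds a toy transcriptome with planted miRNA target sites realizing
#' planned per-position pair states (the site is the reverse complement of
#' the miRNA with the planned edits, laid out in the cleavage geometry used
#' by [extract_site()]), degradome reads whose 5' ends mark the planted
#' cleavage coordinates, an sRNA sample containing the miRNAs, and a
#' ground-truth manifest. Identical seed and config give byte-identical
#' files.
#'
#' @param config from [fixture_config()].
#' @param seed integer seed.
#' @param dir optional output directory; when given, writes
#'   `transcriptome.fa`, `mirnas.fa`, `srna.fa`, `degradome.fa` (the last
#'   two abundance-collapsed) and `manifest.tsv`.
#' @return list with `mirnas`, `known` (annotation table with clades),
#'   `transcriptome`, `srna`, `degradome` ([read_set()]s), `manifest`, and
#'   `dir`.
#' @export
generate_fixture <- function(config = fixture_config(), seed = 1L, dir = NULL) {
  if (config$n_interactions > config$n_transcripts)
    stop("need at least one transcript per planted interaction")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old))
    suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  L <- config$mirna_len
  nt <- c("A", "C", "G", "U")
  rand_seq <- function(n) paste(sample(nt, n, replace = TRUE), collapse = "")

  mirnas <- vapply(seq_len(config$n_mirnas), function(i) rand_seq(L),
                   character(1))
  mirna_ids <- sprintf("ath-syn%03d", seq_len(config$n_mirnas))
  tx_len <- sample(seq(config$transcript_len[1], config$transcript_len[2]),
                   config$n_transcripts, replace = TRUE)
  transcripts <- vapply(tx_len, rand_seq, character(1))
  names(transcripts) <- sprintf("SYNT%04d.1", seq_len(config$n_transcripts))

  plans <- config$interactions
  if (is.null(plans))
    plans <- lapply(seq_len(config$n_interactions), function(i)
      draw_plan(i, mirnas, L, config))

  manifest <- vector("list", length(plans))
  for (i in seq_along(plans)) {
    plan <- plans[[i]]
    mseq <- mirnas[plan$mirna]
    realized <- realize_site(mseq, plan)
    tx <- transcripts[[i]]
    n3 <- realized$n_before_anchor
    t <- sample(seq(n3 + 5L, nchar(tx) - L - 15L), 1L)
    start <- t - n3
    substr(tx, start, start + nchar(realized$site) - 1L) <- realized$site
    transcripts[[i]] <- tx
    manifest[[i]] <- data.frame(
      mirna_id = mirna_ids[plan$mirna], mirna_seq = mseq,
      transcript_id = names(transcripts)[i], cleavage_position = t,
      states = realized$states, score = score_duplex(realized$states),
      peak_abundance = plan$peak_abundance, planned_category = 0L,
      subset = plan$subset %||% "default", stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, manifest)

  ## degradome: planted cleavage products + optional background degradation
  deg_seq <- character(0); deg_ab <- integer(0)
  for (i in seq_len(nrow(manifest))) {
    tx <- transcripts[[manifest$transcript_id[i]]]
    t <- manifest$cleavage_position[i]
    deg_seq <- c(deg_seq, substr(tx, t, min(t + 19L, nchar(tx))))
    deg_ab <- c(deg_ab, manifest$peak_abundance[i])
  }
  if (config$background_rate > 0) {
    for (id in names(transcripts)) {
      tx <- transcripts[[id]]
      npos <- nchar(tx) - 19L
      hits <- which(stats::runif(npos) < config$background_rate)
      for (p in hits) {
        deg_seq <- c(deg_seq, substr(tx, p, p + 19L))
        deg_ab <- c(deg_ab, 1L + stats::rgeom(1L, config$background_geom_p))
      }
    }
  }
  degradome <- read_set(deg_seq, deg_ab, kind = "degradome")

  ## sRNA sample: the miRNAs plus low-abundance random reads
  srna_seq <- mirnas
  srna_ab <- sample(seq(config$srna_abundance[1], config$srna_abundance[2]),
                    config$n_mirnas, replace = TRUE)
  if (config$n_background_srna > 0) {
    srna_seq <- c(srna_seq, vapply(seq_len(config$n_background_srna),
                                   function(i) rand_seq(L), character(1)))
    srna_ab <- c(srna_ab, sample(1:4, config$n_background_srna,
                                 replace = TRUE))
  }
  srna <- read_set(srna_seq, srna_ab, kind = "sRNA")

  known <- fixture_annotation(mirna_ids, mirnas, config)

  out <- list(
    mirnas = data.frame(id = mirna_ids, sequence = mirnas,
                        stringsAsFactors = FALSE),
    known = known, transcriptome = transcripts, srna = srna,
    degradome = degradome, manifest = manifest, dir = dir
  )
  if (!is.null(dir)) write_fixture(out, dir)
  out
}

## default interaction plans: a few mismatches/G:U wobbles inside the
## permissive bounds; in two-subset mode the "specific" half concentrates
## edits at the miRNA 5' end (incl. position 10) and the "conserved" half
## at the 3' end.
draw_plan <- function(i, mirnas, L, config) {
  mseq <- strsplit(mirnas[i], "")[[1L]]
  subset <- if (!config$two_subsets) "default"
    else if (i <= length(mirnas) / 2) "conserved" else "specific"
  ## defect pools keep the two 3'-terminal positions clean so the planted
  ## alignment is also the optimal one (no bulge rescue off the site flank)
  pool_mm <- switch(subset,
    default = c(1L, 14:(L - 2L)),
    conserved = c(1L, 15:(L - 2L)),
    specific = c(1L, 5L, 8L, 9L, 10L, 14:(L - 2L))
  )
  n_mm <- sample(0:2, 1L)
  mm_pos <- sort(pool_mm[sample.int(length(pool_mm), n_mm)])
  gu_ok <- setdiff(which(mseq %in% c("G", "U")),
                   c(mm_pos, 10L, 11L, L - 1L, L))
  n_gu <- min(sample(0:2, 1L), length(gu_ok))
  gu_pos <- sort(gu_ok[sample.int(length(gu_ok), n_gu)])
  list(
    mirna = i, mm_pos = mm_pos, gu_pos = gu_pos, gap_pos = integer(0),
    peak_abundance = sample(seq(config$peak_abundance[1],
                                config$peak_abundance[2]), 1L),
    subset = subset
  )
}

## Build the target-site string (transcript orientation, 5'->3') realizing
## a planned state vector; gap_pos plants miRNA-side bulges (no target
## nucleotide emitted). Returns the site, its states, and the number of
## site nucleotides preceding the anchor (miRNA position 10) so the caller
## can place the cleavage coordinate.
realize_site <- function(mirna_seq, plan) {
  m <- strsplit(normalize_rna(mirna_seq), "")[[1L]]
  L <- length(m)
  wc <- c(A = "U", C = "G", G = "C", U = "A")
  gu <- c(G = "U", U = "G")
  states <- rep("=", L)
  states[plan$mm_pos] <- "x"
  states[plan$gu_pos] <- "o"
  states[plan$gap_pos] <- "-"
  if (states[10L] == "-" )
    stop("a gap cannot be planted at the anchor position 10")
  if (any(states[plan$gu_pos] == "o" & !(m[plan$gu_pos] %in% c("G", "U"))))
    stop("G:U wobble planned at a position where the miRNA has neither G nor U")
  chars <- character(0)
  n_before <- 0L
  for (p in seq(L, 1L)) {                      # increasing transcript coords
    ch <- switch(states[p],
      "=" = wc[[m[p]]],
      "o" = gu[[m[p]]],
      "x" = sample(setdiff(c("A", "C", "G", "U"),
                           c(wc[[m[p]]], if (m[p] %in% names(gu)) gu[[m[p]]])),
                   1L),
      "-" = NA_character_
    )
    if (!is.na(ch)) {
      chars <- c(chars, ch)
      if (p > 10L) n_before <- n_before + 1L
    }
  }
  list(site = paste(chars, collapse = ""),
       states = paste(states, collapse = ""),
       n_before_anchor = n_before)
}

## Known-miRNA annotation for fixture candidates: in two-subset mode the
## conserved half gets variants in two clades, the specific half one.
fixture_annotation <- function(ids, seqs, config) {
  if (!config$two_subsets)
    return(data.frame(id = ids, sequence = seqs, species = "ath",
                      clade = "Brassicaceae", stringsAsFactors = FALSE))
  half <- seq_along(ids) <= length(ids) / 2
  extra <- data.frame(
    id = paste0(sub("^ath", "osa", ids[half]), "-like"),
    sequence = seqs[half], species = "osa", clade = "Poaceae",
    stringsAsFactors = FALSE
  )
  rbind(
    data.frame(id = ids, sequence = seqs, species = "ath",
               clade = "Brassicaceae", stringsAsFactors = FALSE),
    extra
  )
}

write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- function(ids, seqs, path, dna = TRUE) {
    if (dna) seqs <- rna_to_dna(seqs)
    writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  }
  fa(names(fx$transcriptome), unname(fx$transcriptome),
     file.path(dir, "transcriptome.fa"))
  fa(fx$known$id, fx$known$sequence, file.path(dir, "mirnas.fa"), dna = FALSE)
  write_collapsed_fasta(fx$srna, file.path(dir, "srna.fa"))
  write_collapsed_fasta(fx$degradome, file.path(dir, "degradome.fa"))
  utils::write.table(fx$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
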