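#' Non-redundant read set
#'
#' A `read_set` stores unique sequences with summed abundances, the standard
#' non-redundant representation of an sRNA or degradome sample. Sequences are
#' held internally in the RNA alphabet (`T` is converted to `U` on input).
#'
#' @param sequences character vector of sequences (may contain duplicates;
#'   duplicates are merged with summed abundance).
#' @param abundances integer vector of per-sequence counts, recycled to the
#'   length of `sequences`; defaults to 1.
#' @param kind `"sRNA"` or `"degradome"`.
#' @return An object of class `read_set`: a list with a `reads` data frame
#'   (columns `sequence`, `abundance`) and the sample `kind`.
#' @export
read_set <- function(sequences, abundances = 1L, kind = c("sRNA", "degradome")) {
  kind <- match.arg(kind)
  stopifnot(is.character(sequences))
  abundances <- rep_len(as.integer(abundances), length(sequences))
  if (length(sequences) && any(abundances < 1L))
    stop("read abundances must be >= 1")
  if (length(sequences) && any(nchar(sequences) < 1L))
    stop("zero-length read sequence")
  seqs <- normalize_rna(sequences)
  ab <- if (length(seqs)) {
    tab <- tapply(abundances, seqs, sum)
    tab[order(names(tab))]
  } else {
    integer(0)
  }
  structure(
    list(
      reads = data.frame(
        sequence = as.character(names(ab)),
        abundance = as.integer(unname(ab)),
        stringsAsFactors = FALSE
      ),
      kind = kind
    ),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf(
    "<read_set> %s: %d unique sequences, total abundance %d\n",
    x$kind, nrow(x$reads), total_abundance(x)
  ))
  invisible(x)
}

#' @rdname read_set
#' @param x a `read_set`.
#' @export
total_abundance <- function(x) {
  stopifnot(inherits(x, "read_set"))
  sum(x$reads$abundance)
}

## Uppercase and move to the RNA alphabet; validates characters.
normalize_rna <- function(x) {
  x <- chartr("acgutn", "ACGUUN", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,U/T,N}: ",
         x[which(bad)[1L]])
  x
}

## DNA view of an RNA-alphabet sequence (for file output, if ever needed).
rna_to_dna <- function(x) chartr("U", "T", x)

#' Read sequencing reads into a non-redundant read set
#'
#' Accepts plain FASTA, FASTQ, or abundance-collapsed FASTA where the header
#' carries the read count as a final underscore-delimited integer
#' (`>name_17`). Duplicate sequences are merged with summed abundances;
#' FASTQ quality strings are ignored.
#'
#' @param path input file (optionally gzip-compressed).
#' @param format `"fasta"`, `"fastq"` or `"collapsed"`; `"auto"` guesses
#'   FASTQ from a leading `@` and otherwise treats FASTA headers of the form
#'   `name_N` as collapsed counts (a bare FASTA record simply counts 1, so
#'   the collapsed reader is a strict generalization).
#' @param kind passed to [read_set()].
#' @return a [read_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq", "collapsed"),
                           kind = c("sRNA", "degradome")) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    con <- gzfile(path, "rt")
    first <- readLines(con, n = 1L)
    close(con)
    if (!length(first)) stop("empty input file: ", path)
    format <- if (startsWith(first, "@")) "fastq" else "collapsed"
  }
  ss <- tryCatch(
    ## BStringSet accepts both DNA (T) and RNA (U) alphabets; normalize_rna
    ## canonicalizes afterwards.
    Biostrings::readBStringSet(path,
                               format = if (format == "fastq") "fastq" else "fasta"),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(Biostrings::width(ss) == 0L))
    stop("empty sequence record in '", path, "' (record ",
         which(Biostrings::width(ss) == 0L)[1L], ")")
  seqs <- as.character(ss)
  counts <- if (format == "collapsed") collapsed_counts(names(ss)) else
    rep(1L, length(ss))
  read_set(seqs, counts, kind = kind)
}

## ">label_COUNT": COUNT is the final underscore-delimited integer; absent or
## non-numeric suffix means abundance 1.
collapsed_counts <- function(headers) {
  ids <- sub("\\s.*$", "", headers)
  suffix <- sub("^.*_", "", ids)
  n <- suppressWarnings(as.integer(suffix))
  n[!grepl("_", ids) | is.na(n) | n < 1L] <- 1L
  n
}

#' Write a read set as abundance-collapsed FASTA
#'
#' Headers have the form `>rK_N` where `N` is the read abundance, the
#' convention [read_sequences()] parses back, so write/read round-trips
#' exactly.
#'
#' @param rs a [read_set()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  lines <- character(0)
  if (nrow(rs$reads))
    lines <- rbind(
      sprintf(">r%d_%d", seq_len(nrow(rs$reads)), rs$reads$abundance),
      rs$reads$sequence
    )
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Read a reference transcriptome
#'
#' @param path FASTA file; the transcript id is the first
#'   whitespace-delimited token of each header.
#' @return named character vector of RNA-alphabet transcript sequences.
#' @export
read_transcriptome <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ss <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (any(Biostrings::width(ss) == 0L))
    stop("empty sequence record in '", path, "'")
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate transcript id(s): ", paste(dup, collapse = ", "))
  seqs <- normalize_rna(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Read known mature miRNAs with species/clade metadata
#'
#' Parses a miRBase-style mature FASTA (`>ath-miR156a MIMAT0000166 ...`).
#' The species code is the prefix before the first `-`; clades are assigned
#' through `clade_map` (see [default_clade_map()]).
#'
#' @param path mature-miRNA FASTA.
#' @param clade_map named character vector: species prefix -> clade.
#' @return data frame with columns `id`, `sequence`, `species`, `clade`.
#'   Sequences outside 19-25 nt raise a warning but are kept.
#' @export
read_mirnas <- function(path, clade_map = default_clade_map()) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- normalize_rna(as.character(ss))
  len <- nchar(seqs)
  if (any(len < 19L | len > 25L))
    warning(sum(len < 19L | len > 25L),
            " mature miRNA sequence(s) outside the usual 19-25 nt range")
  species <- sub("-.*$", "", ids)
  clade <- unname(clade_map[species])
  data.frame(
    id = ids, sequence = seqs, species = species,
    clade = ifelse(is.na(clade), NA_character_, clade),
    stringsAsFactors = FALSE
  )
}

#' Built-in species-prefix to clade map
#'
#' Covers the miRBase species prefixes used in typical plant analyses; users
#' can extend or replace it (names are miRBase three-letter prefixes).
#'
#' @return named character vector.
#' @export
default_clade_map <- function() {
  c(
    ath = "Brassicaceae", aly = "Brassicaceae", bra = "Brassicaceae",
    osa = "Poaceae", tae = "Poaceae", zma = "Poaceae", bdi = "Poaceae",
    sbi = "Poaceae", hvu = "Poaceae",
    gma = "Fabaceae", mtr = "Fabaceae", lja = "Fabaceae",
    sly = "Solanaceae", stu = "Solanaceae", nta = "Solanaceae",
    atr = "Amborellaceae",
    ptc = "Salicaceae", vvi = "Vitaceae", csi = "Rutaceae",
    smo = "Selaginellaceae", ppt = "Funariaceae"
  )
}

#' Read a validated-interaction table
#'
#' Tab-delimited with a header row; requires columns `mirna_id`,
#' `mirna_sequence`, `transcript_id`, `cleavage_position` (extra columns are
#' ignored). Cleavage coordinates are 1-based on the transcript.
#'
#' @param path TSV file.
#' @return data frame with the four required columns.
#' @export
read_validated <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("mirna_id", "mirna_sequence", "transcript_id", "cleavage_position")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("validated-interaction table is missing column(s): ",
         paste(miss, collapse = ", "))
  pos <- suppressWarnings(as.integer(tab$cleavage_position))
  bad <- is.na(pos) | pos != as.numeric(tab$cleavage_position)
  if (any(bad))
    stop("non-integer cleavage_position in row ", which(bad)[1L])
  if (any(pos < 1L))
    stop("cleavage_position must be >= 1 (row ", which(pos < 1L)[1L], ")")
  data.frame(
    mirna_id = as.character(tab$mirna_id),
    mirna_sequence = normalize_rna(tab$mirna_sequence),
    transcript_id = as.character(tab$transcript_id),
    cleavage_position = pos,
    stringsAsFactors = FALSE
  )
}
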