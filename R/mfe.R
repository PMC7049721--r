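## Nearest-neighbor duplex hybridization energy over a fixed alignment.
##
## Uses published Turner 2004 thermodynamic constants (37C, kcal/mol):
## stacking energies for the six pair types, duplex initiation 4.10,
## terminal AU/GU penalty 0.50, bulge and internal-loop initiations and the
## asymmetry (NINIO) term. Stabilizing values are the published ones;
## destabilizing (positive) G:U-on-G:U stacks are clamped at 0 so that
## introducing a mismatch can never lower the duplex energy, keeping the
## MFE ratio monotone in the number of defects.

.pair_types <- c("CG", "GC", "GU", "UG", "AU", "UA")

.stack_dg <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,   # CG
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,   # GC
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,   # GU
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,   # UG
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,   # AU
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30    # UA
), nrow = 6, byrow = TRUE, dimnames = list(.pair_types, .pair_types))

.duplex_init <- 4.10
.terminal_au <- 0.50
.bulge_init <- c(3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80, 4.90)
.internal_init <- c(NA, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40,
                    2.50, 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10,
                    3.20, 3.30)
.ninio_m <- 0.60
.ninio_max <- 3.00

## Exterior (terminal) mismatch energies: stabilization from the first
## unpaired nucleotides outside the outermost pair of the duplex, indexed
## [pair type, 5' unpaired nt, 3' unpaired nt] with nt order N,A,C,G,U.
.nt5 <- c("N", "A", "C", "G", "U")
.mismatch_ext <- array(c(
  # CG: rows nt5 (N,A,C,G,U) x cols nt3
  -0.50,-1.10,-0.70,-1.10,-0.50, -1.10,-1.10,-1.50,-1.30,-1.50,
  -0.50,-1.10,-0.70,-1.10,-0.50, -1.40,-1.60,-1.50,-1.40,-1.50,
  -0.70,-1.10,-1.00,-1.10,-0.70,
  # GC
  -0.80,-1.00,-1.10,-1.00,-0.80, -1.40,-1.50,-1.50,-1.40,-1.50,
  -0.80,-1.00,-1.10,-1.00,-0.80, -1.40,-1.40,-1.50,-1.60,-1.50,
  -1.00,-1.00,-1.40,-1.00,-1.20,
  # GU
  -0.50,-0.50,-0.60,-0.70,-0.50, -0.80,-1.00,-0.80,-1.10,-0.80,
  -0.50,-0.70,-0.60,-0.70,-0.50, -0.50,-0.50,-0.80,-0.80,-0.80,
  -0.50,-0.70,-0.60,-0.70,-0.50,
  # UG
  -0.30,-0.30,-0.70,-0.60,-0.60, -0.30,-0.30,-1.00,-0.80,-1.00,
  -0.60,-0.60,-0.70,-0.60,-0.70, -0.60,-0.60,-1.00,-0.80,-1.00,
  -0.60,-0.60,-0.80,-0.60,-0.60,
  # AU
  -0.50,-0.70,-0.60,-0.70,-0.50, -0.80,-1.00,-0.80,-1.10,-0.80,
  -0.50,-0.70,-0.60,-0.70,-0.50, -0.80,-1.10,-0.80,-1.20,-0.80,
  -0.50,-0.70,-0.60,-0.70,-0.50,
  # UA
  -0.60,-0.60,-0.70,-0.60,-0.70, -0.80,-0.80,-1.00,-0.80,-1.00,
  -0.60,-0.60,-0.70,-0.60,-0.70, -0.80,-0.80,-1.00,-0.80,-1.00,
  -0.60,-0.60,-0.80,-0.60,-0.80
), dim = c(5, 5, 6),
  dimnames = list(.nt5, .nt5, .pair_types))

loop_extrapolate <- function(tab, n) {
  if (n <= length(tab) && !is.na(tab[n])) return(tab[n])
  # logarithmic size extrapolation beyond the tabulated range
  tab[length(tab)] + 1.08 * log(n / length(tab))
}

pair_type <- function(x, y) {
  pt <- paste0(x, y)
  if (!pt %in% .pair_types) NA_character_ else pt
}

stack_energy <- function(m1, t1, m2, t2) {
  outer <- pair_type(m1, t1)
  inner <- pair_type(t2, m2)   # inner pair enters the table reversed
  if (is.na(outer) || is.na(inner)) return(0)
  min(.stack_dg[outer, inner], 0)
}

terminal_penalty <- function(m_nt, t_nt) {
  if (pair_type(m_nt, t_nt) %in% c("AU", "UA", "GU", "UG")) .terminal_au else 0
}

#' Nearest-neighbor duplex energy of a fixed alignment
#'
#' Helix stacks are summed with the Turner stacking table; interruptions are
#' charged as bulge loops (gaps only; a single-nucleotide bulge retains the
#' flanking stack) or internal loops (size-dependent initiation plus an
#' asymmetry term). Unpaired columns outside the outermost paired columns
#' contribute nothing (they are outside the duplex).
#'
#' @param mirna_seq miRNA sequence 5' to 3'.
#' @param target_seq per-position target nucleotides as returned by
#'   [align_duplex()] (`-` marks bulges / off-site positions).
#' @param states compact state string from [align_duplex()].
#' @return energy in kcal/mol (negative = stable); 0 when nothing pairs.
#' @export
nn_duplex_energy <- function(mirna_seq, target_seq, states) {
  m <- strsplit(normalize_rna(mirna_seq), "")[[1L]]
  tv <- strsplit(target_seq, "")[[1L]]
  v <- states_vector(states)
  stopifnot(length(m) == length(v), length(tv) == length(v))
  idx <- which(v %in% c("=", "o"))
  if (!length(idx)) return(0)
  a <- idx[1L]; b <- idx[length(idx)]
  E <- .duplex_init +
    terminal_penalty(m[a], tv[a]) + terminal_penalty(m[b], tv[b])
  ## stabilization by the first unpaired nucleotides outside the duplex
  nt_or_N <- function(x) if (x %in% c("A", "C", "G", "U")) x else "N"
  if (a > 1L && !is.na(pair_type(m[a], tv[a])))
    E <- E + .mismatch_ext[nt_or_N(m[a - 1L]), nt_or_N(tv[a - 1L]),
                           pair_type(m[a], tv[a])]
  if (b < length(v) && !is.na(pair_type(tv[b], m[b])))
    E <- E + .mismatch_ext[nt_or_N(tv[b + 1L]), nt_or_N(m[b + 1L]),
                           pair_type(tv[b], m[b])]
  for (k in seq_along(idx)[-1L]) {
    a <- idx[k - 1L]; b <- idx[k]
    if (b == a + 1L) {
      E <- E + stack_energy(m[a], tv[a], m[b], tv[b])
    } else {
      between <- v[(a + 1L):(b - 1L)]
      n_x <- sum(between == "x")
      n_g <- sum(between == "-")
      if (n_x == 0L) {
        E <- E + loop_extrapolate(.bulge_init, n_g)
        if (n_g == 1L) E <- E + stack_energy(m[a], tv[a], m[b], tv[b])
      } else if (n_x == 1L && n_g == 0L) {
        ## 1x1 interior loop: typical tabulated value for WC-closed loops
        E <- E + 0.55
      } else {
        size <- 2L * n_x + n_g
        E <- E + loop_extrapolate(.internal_init, size) +
          min(.ninio_max, .ninio_m * n_g)
      }
    }
  }
  E
}

## Duplex energy minimized over short terminal trims: a helix extension
## beyond a defect is only kept when it stabilizes the duplex (a folding
## engine would leave such ends unpaired). Trims of up to three outermost
## paired columns per end are considered.
nn_duplex_mfe <- function(mirna_seq, target_seq, states) {
  v <- states_vector(states)
  idx <- which(v %in% c("=", "o"))
  if (!length(idx)) return(nn_duplex_energy(mirna_seq, target_seq, states))
  lo_opts <- idx[seq_len(min(4L, length(idx)))]
  hi_opts <- idx[length(idx) - seq_len(min(4L, length(idx))) + 1L]
  best <- Inf
  for (lo in lo_opts) for (hi in hi_opts) {
    if (hi < lo) next
    vt <- v
    vt[idx[idx < lo | idx > hi]] <- "x"   # unpair trimmed columns
    e <- nn_duplex_energy(mirna_seq, target_seq, paste(vt, collapse = ""))
    if (e < best) best <- e
  }
  best
}

rna_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
}

#' Duplex MFE ratio
#'
#' Energy of the observed duplex divided by the energy of the miRNA paired
#' with its perfect reverse complement, computed with the same backend.
#' Since both energies are negative and the perfect duplex is minimal, the
#' ratio lies in (0, 1] (clamped at 0.01 for duplexes with essentially no
#' hybridization).
#'
#' @inheritParams nn_duplex_energy
#' @param backend `"nn"` for the built-in nearest-neighbor model or
#'   `"vienna"` for the external `RNAduplex` program.
#' @return ratio in `(0, 1]`.
#' @export
duplex_mfe_ratio <- function(mirna_seq, target_seq, states,
                             backend = c("nn", "vienna")) {
  backend <- match.arg(backend)
  mirna_seq <- normalize_rna(mirna_seq)
  if (backend == "nn") {
    L <- nchar(mirna_seq)
    ## per-position complement (target vector indexed by miRNA position)
    perfect <- nn_duplex_energy(mirna_seq, chartr("ACGU", "UGCA", mirna_seq),
                                strrep("=", L))
    obs <- nn_duplex_mfe(mirna_seq, target_seq, states)
  } else {
    e <- vienna_duplex_energy(c(mirna_seq, mirna_seq),
                              c(aligned_target_strand(target_seq),
                                rna_revcomp(mirna_seq)))
    obs <- e[1L]; perfect <- e[2L]
  }
  if (perfect >= 0) stop("degenerate perfect duplex for ", mirna_seq)
  if (obs >= 0) return(0.01)
  min(1, max(0.01, obs / perfect))
}

## Per-position target vector lists the nucleotide opposite miRNA position
## p; the physical target strand 5'->3' is that sequence reversed.
aligned_target_strand <- function(target_seq) {
  gsub("-", "", rev_chars(target_seq))
}

rev_chars <- function(x) {
  paste(rev(strsplit(x, "")[[1L]]), collapse = "")
}

#' Batched duplex energies from the external RNAduplex program
#'
#' @param seq1,seq2 equal-length character vectors of strand pairs.
#' @return numeric vector of duplex energies (kcal/mol).
#' @export
vienna_duplex_energy <- function(seq1, seq2) {
  stopifnot(length(seq1) == length(seq2))
  exe <- Sys.which("RNAduplex")
  if (exe == "") stop("RNAduplex not found on PATH; use backend = \"nn\"")
  input <- as.vector(rbind(seq1, seq2))
  out <- system2(exe, c("--noconv"), stdout = TRUE, input = input)
  hits <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\)\\s*$", out))
  if (length(hits) != length(seq1))
    stop("RNAduplex returned ", length(hits), " energies for ",
         length(seq1), " duplexes")
  as.numeric(gsub("[()\\s]", "", hits, perl = TRUE))
}
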