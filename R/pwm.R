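# Position weight matrices: construction, MEME minimal-format IO, and a
# brute-force log-odds scanner used as the reference oracle for generation
# and variant tests.

#' Construct a motif model
#'
#' A PWM over columns A, C, G, T. Cells are floored at a pseudo-probability
#' of 0.01 (rows renormalized) so log-odds stay finite. Typical regulatory
#' motifs are 6--20 bp wide.
#'
#' @param name Motif name.
#' @param pwm width x 4 matrix of column probabilities (columns A, C, G, T);
#'   rows must sum to 1 within tolerance before flooring.
#' @param floor Minimum cell probability.
#' @return A `motif_model` list with fields `name`, `pwm`, `width`.
#' @export
motif_model <- function(name, pwm, floor = 0.01) {
  pwm <- as.matrix(pwm)
  if (ncol(pwm) != 4) rlang::abort("pwm must have 4 columns (A, C, G, T)")
  # tolerance admits rows regenerated from fixed-precision text formats
  if (any(abs(rowSums(pwm) - 1) > 1e-4)) {
    rlang::abort("pwm rows must sum to 1")
  }
  pwm <- pmax(pwm, floor)
  pwm <- pwm / rowSums(pwm)
  colnames(pwm) <- BASES
  structure(list(name = name, pwm = pwm, width = nrow(pwm)), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s, width %d, consensus %s\n",
              x$name, x$width, consensus_seq(x)))
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param motif A [motif_model()].
#' @return Character string of column-wise argmax bases.
#' @export
consensus_seq <- function(motif) {
  paste(BASES[apply(motif$pwm, 1, which.max)], collapse = "")
}

pwm_from_consensus <- function(name, consensus, dominant = 0.94) {
  chars <- seq_chars(consensus)
  dominant <- rep_len(dominant, length(chars))
  pwm <- matrix(0, nrow = length(chars), ncol = 4, dimnames = list(NULL, BASES))
  for (i in seq_along(chars)) {
    pwm[i, ] <- (1 - dominant[i]) / 3
    pwm[i, chars[i]] <- dominant[i]
  }
  motif_model(name, pwm)
}

#' Default synthetic motif set
#'
#' Four hand-specified PWMs of widths 6, 8, 10 and 12 with one dominant base
#' per column (probabilities cycling through `dominant`, information content
#' about 1.5 bits/column on average — real binding sites mix strong and
#' weaker columns), loosely patterned on AP-1, E-box, GC-box and forkhead
#' consensus sites.
#'
#' @param dominant Dominant-base probabilities, recycled along the columns.
#' @return Named list of [motif_model()]s.
#' @export
default_motifs <- function(dominant = c(0.96, 0.90, 0.94, 0.92)) {
  list(
    ap1_like = pwm_from_consensus("ap1_like", "TGACTC", dominant),
    ebox_like = pwm_from_consensus("ebox_like", "CACGTGAC", dominant),
    gcbox_like = pwm_from_consensus("gcbox_like", "GGGGCGGGGC", dominant),
    fox_like = pwm_from_consensus("fox_like", "TGTTTACTTTGC", dominant)
  )
}

# Per-offset forward-strand log-odds scores of a motif over an uppercase
# token id vector; N positions (id 5) contribute 0.
scan_log_odds <- function(ids, pwm, log_bg) {
  w <- nrow(pwm)
  L <- length(ids)
  n_off <- L - w + 1L
  lp <- log(pwm)
  scores <- numeric(n_off)
  for (o in seq_len(n_off)) {
    window <- ids[o:(o + w - 1L)]
    contrib <- ifelse(window <= 4L,
      lp[cbind(seq_len(w), pmin(window, 4L))] - log_bg[pmin(window, 4L)], 0
    )
    scores[o] <- sum(contrib)
  }
  scores
}

#' Best PWM log-odds score of a sequence
#'
#' Maximum over all offsets and both strands of
#' `sum(log(pwm / background))`. `N` positions contribute 0 (with a note the
#' first time). Deterministic; used as the reference oracle in generation
#' and variant tests.
#'
#' @param seq DNA string with `nchar(seq) >= motif$width`.
#' @param motif A [motif_model()].
#' @param background Length-4 background frequencies (A, C, G, T).
#' @return Scalar score, with attributes `offset` (0-based) and `strand` of
#'   the best placement.
#' @export
pwm_log_odds_score <- function(seq, motif, background = rep(0.25, 4)) {
  stopifnot(abs(sum(background) - 1) < 1e-6)
  if (nchar(seq) < motif$width) {
    rlang::abort("sequence shorter than motif width")
  }
  ids <- encode_tokens(seq)
  if (any(ids == N_ID)) {
    rlang::inform("N positions contribute 0 to the PWM score", .frequency = "once",
                  .frequency_id = "motiflm_pwm_n")
  }
  log_bg <- log(background)
  fwd <- scan_log_odds(ids, motif$pwm, log_bg)
  rev_ids <- encode_tokens(reverse_complement(seq))
  rev <- scan_log_odds(rev_ids, motif$pwm, log_bg)
  all_scores <- c(fwd, rev)
  best <- which.max(all_scores)
  n_off <- length(fwd)
  strand <- if (best <= n_off) "+" else "-"
  off <- if (best <= n_off) best - 1L else {
    # offset on the reverse strand, mapped back to forward coordinates
    nchar(seq) - (best - n_off - 1L) - motif$width
  }
  structure(all_scores[best], offset = as.integer(off), strand = strand)
}

#' Write motifs in MEME minimal format
#'
#' @param motifs List of [motif_model()]s.
#' @param path Output path.
#' @param background Background frequencies recorded in the header.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.5f", BASES, background), collapse = " "), ""
  ), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width
    ), con)
    writeLines(apply(m$pwm, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path MEME file path.
#' @return Named list of [motif_model()]s.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- s + which(grepl("^letter-probability matrix", lines[(s + 1):length(lines)]))[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    pwm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    motifs[[name]] <- motif_model(name, pwm)
  }
  motifs
}
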