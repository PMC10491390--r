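# HMMER3 model header editing: writing calibrated GA/TC/NC cutoff lines.

#' Insert calibrated cutoffs into a HMMER3 model header
#'
#' Rewrites (or inserts) the `GA`, `TC` and `NC` lines of a HMMER3 ASCII
#' model. Existing cutoff lines are removed first, so the operation is
#' idempotent. New lines are placed directly after the `CKSUM` line (or,
#' failing that, before the first `STATS`/`HMM` line) using the HMMER3
#' syntax `GA    <seq> <dom>;` with two-decimal fixed-point values. The
#' `NC` line is omitted when the marker carries no noise cutoff. Everything
#' outside the edited header lines is preserved byte-for-byte.
#'
#' @param model_text character vector of model lines, or a file path.
#' @param marker one markers-table row (list/data.frame with `GA_seq`,
#'   `GA_dom`, `TC_seq`, `TC_dom`, `NC_seq`, `NC_dom`).
#' @return character vector of model lines.
#' @export
annotate_hmm <- function(model_text, marker) {
  lines <- if (length(model_text) == 1L && file.exists(model_text))
    readLines(model_text, warn = FALSE) else model_text
  if (!length(lines) || !grepl("^HMMER3", lines[[1L]]))
    stop("malformed HMMER3 model: line 1 must start with 'HMMER3'")
  hmm_at <- grep("^HMM\\s", lines)
  if (!length(hmm_at))
    stop("malformed HMMER3 model: no 'HMM' table header line found")
  hmm_at <- hmm_at[[1L]]
  header <- lines[seq_len(hmm_at - 1L)]
  body <- lines[hmm_at:length(lines)]

  header <- header[!grepl("^(GA|TC|NC)\\s", header)]
  cutoff <- function(tag, s, d)
    sprintf("%s    %.2f %.2f;", tag, s, d)
  new <- c(cutoff("GA", marker$GA_seq, marker$GA_dom),
           cutoff("TC", marker$TC_seq, marker$TC_dom))
  if (!is.null(marker$NC_seq) && !is.na(marker$NC_seq))
    new <- c(new, cutoff("NC", marker$NC_seq, marker$NC_dom))

  anchor <- grep("^CKSUM\\s", header)
  if (length(anchor)) {
    anchor <- anchor[[1L]]
  } else {
    stats_at <- grep("^STATS\\s", header)
    anchor <- if (length(stats_at)) stats_at[[1L]] - 1L else length(header)
  }
  c(header[seq_len(anchor)], new,
    if (anchor < length(header)) header[(anchor + 1L):length(header)],
    body)
}

#' Read the GA/TC/NC cutoffs back from a HMMER3 model
#'
#' @param model_text character vector of model lines, or a file path.
#' @return named list with `GA_seq`, `GA_dom`, `TC_seq`, `TC_dom`,
#'   `NC_seq`, `NC_dom` (`NA` for an absent NC line).
#' @export
read_hmm_cutoffs <- function(model_text) {
  lines <- if (length(model_text) == 1L && file.exists(model_text))
    readLines(model_text, warn = FALSE) else model_text
  pick <- function(tag) {
    ln <- grep(sprintf("^%s\\s", tag), lines, value = TRUE)
    if (!length(ln)) return(c(NA_real_, NA_real_))
    nums <- regmatches(ln[[1L]], gregexpr("-?[0-9]+\\.?[0-9]*", ln[[1L]]))[[1L]]
    as.numeric(nums[1:2])
  }
  ga <- pick("GA"); tc <- pick("TC"); nc <- pick("NC")
  list(GA_seq = ga[1], GA_dom = ga[2], TC_seq = tc[1], TC_dom = tc[2],
       NC_seq = nc[1], NC_dom = nc[2])
}

#' Annotate a directory of HMMER3 model files in place
#'
#' Each model file `<model_id>.hmm` found in `dir` whose id appears in the
#' markers table gets its cutoff lines rewritten.
#'
#' @param dir directory holding `.hmm` files named by model id.
#' @param markers markers table from [curate_markers()].
#' @return character vector of rewritten file paths, invisibly.
#' @export
annotate_hmm_dir <- function(dir, markers) {
  markers <- as.data.table(markers)
  done <- character(0)
  for (i in seq_len(nrow(markers))) {
    p <- file.path(dir, paste0(markers$model_id[[i]], ".hmm"))
    if (!file.exists(p)) next
    writeLines(annotate_hmm(p, markers[i]), p)
    done <- c(done, p)
  }
  invisible(done)
}

#' Build a minimal synthetic HMMER3 model text
#'
#' A syntactically plausible (not emission-calibrated) two-state amino-acid
#' model used by the fixture generators and tests as a stand-in for a real
#' profile HMM; only the header matters to this package.
#'
#' @param model_id model name written to the `NAME` line.
#' @param leng model length reported in the header.
#' @return character vector of model lines.
#' @export
synthetic_hmm_text <- function(model_id, leng = 2L) {
  aa <- "  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000  2.50000"
  tr <- "  0.01467  4.62483  5.34718  0.61958  0.77255  0.48576  0.95510"
  body <- unlist(lapply(seq_len(leng), function(i) c(
    sprintf("%7d%s %6d x - - -", i, aa, i),
    paste0("       ", aa),
    paste0("       ", tr)
  )))
  c(sprintf("HMMER3/f [3.4 | synthetic]"),
    sprintf("NAME  %s", model_id),
    sprintf("LENG  %d", leng),
    "ALPH  amino",
    "RF    no", "MM    no", "CONS  yes", "CS    no", "MAP   yes",
    "DATE  Mon Jan  1 00:00:00 2024",
    "NSEQ  4",
    "EFFN  2.000000",
    "CKSUM 123456789",
    "STATS LOCAL MSV       -9.0000  0.70000",
    "STATS LOCAL VITERBI   -9.5000  0.70000",
    "STATS LOCAL FORWARD   -3.5000  0.70000",
    "HMM          A        C        D        E        F        G        H        I        K        L        M        N        P        Q        R        S        T        V        W        Y",
    "            m->m     m->i     m->d     i->m     i->i     d->m     d->d",
    paste0("  COMPO", aa),
    paste0("       ", aa),
    paste0("       ", tr),
    body,
    "//")
}
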