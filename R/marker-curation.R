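# Selection of taxon-informative marker models from homology-search hits
# and calibration of per-model GA/TC/NC bit-score thresholds.

#' Per-taxon best-score ranges for one model
#'
#' Step one of the calibration: within the hits of a single model, keep only
#' the highest full-sequence bit score per source taxid, lift each taxid to
#' its ancestor at `rank` (taxids whose lineage lacks that rank drop out of
#' the competition), and summarise every group by the lowest and highest of
#' the kept per-taxid best scores.
#'
#' @param hits data.frame with at least `taxid` and `full_score` (one model's
#'   hits; an optional `model_id` column is ignored here).
#' @param tree a `taxonomy_tree` resolving every `taxid`.
#' @param rank one of `WORK_RANKS`.
#' @return data.table with columns `taxon`, `low`, `high`, `n_taxids`
#'   (possibly zero rows).
#' @export
best_scores_by_taxon <- function(hits, tree, rank) {
  stopifnot(rank %in% WORK_RANKS)
  hits <- as.data.table(hits)
  if (!nrow(hits))
    return(data.table(taxon = character(), low = numeric(),
                      high = numeric(), n_taxids = integer()))
  .check_taxid(tree, hits$taxid)
  best <- hits[, .(best = max(full_score)), by = .(taxid = as.character(taxid))]
  lin <- lineage_table(tree, best$taxid)
  best[, taxon := lin[[rank]]]
  best <- best[!is.na(taxon)]
  if (!nrow(best))
    return(data.table(taxon = character(), low = numeric(),
                      high = numeric(), n_taxids = integer()))
  out <- best[, .(low = min(best), high = max(best), n_taxids = .N),
              by = taxon]
  setorder(out, taxon)
  out[]
}

#' Select the informative rank/taxon for one model
#'
#' Ranks are tried genus, subfamily, family, order. At each rank the best
#' taxon is the one with the highest upper score bound (ties: higher lower
#' bound, then lexicographically smaller id). The model is informative at
#' that rank iff it hit a single taxon there, or the best taxon's lower
#' bound strictly exceeds every other taxon's upper bound. On success S1 is
#' the best taxon's lower bound and S2 the maximum upper bound over the
#' remaining taxa (`NA` when there are none). Models failing at every rank
#' are non-informative.
#'
#' @param hits one model's hits (`taxid`, `full_score`), already filtered at
#'   the reporting E-value (<= 1e-3) upstream.
#' @param tree a `taxonomy_tree`.
#' @return a list `(rank, taxon, S1, S2)` or `NULL` when non-informative.
#' @export
select_informative <- function(hits, tree) {
  for (rank in WORK_RANKS) {
    rg <- best_scores_by_taxon(hits, tree, rank)
    if (!nrow(rg)) next
    setorder(rg, -high, -low, taxon)
    best <- rg[1L]
    others <- rg[-1L]
    if (!nrow(others))
      return(list(rank = rank, taxon = best$taxon, S1 = best$low,
                  S2 = NA_real_))
    if (best$low > max(others$high))
      return(list(rank = rank, taxon = best$taxon, S1 = best$low,
                  S2 = max(others$high)))
  }
  NULL
}

#' Derive the six GA/TC/NC thresholds from S1/S2
#'
#' Per-sequence gathering and trusted cutoffs are both S1. The per-domain
#' cutoff is S1 trimmed by three bits, but the trim is only applied when it
#' does not drop S1 to or below S2 (with S2 absent the trim always applies).
#' The noise cutoff is S2 for both components, omitted when S2 is absent.
#'
#' @param S1 minimum bit score within the target taxon's range.
#' @param S2 maximum bit score over the other taxa, or `NA`.
#' @return named list: `GA_seq`, `GA_dom`, `TC_seq`, `TC_dom`, `NC_seq`,
#'   `NC_dom` (the NC pair is `NA` when S2 is absent).
#' @export
derive_thresholds <- function(S1, S2 = NA_real_) {
  stopifnot(is.finite(S1))
  if (!is.na(S2) && S2 >= S1)
    stop("calibration error: S2 (", S2, ") must be < S1 (", S1, ")")
  dom <- if (is.na(S2) || (S1 - 3) > S2) S1 - 3 else S1
  list(GA_seq = S1, GA_dom = dom, TC_seq = S1, TC_dom = dom,
       NC_seq = as.numeric(S2), NC_dom = as.numeric(S2))
}

#' Curate informative markers from a full hits table
#'
#' Splits a curation hits table by model, runs [select_informative()] and
#' [derive_thresholds()], and returns one row per informative model.
#'
#' @param hits data.frame with `model_id`, `taxid`, `full_score` and
#'   optionally `evalue` (rows with `evalue` > `evalue_max` are discarded
#'   first).
#' @param tree a `taxonomy_tree`.
#' @param evalue_max reporting E-value cutoff applied when an `evalue`
#'   column is present (default 1e-3).
#' @return data.table with columns `model_id`, `rank`, `taxon`, `S1`, `S2`,
#'   `GA_seq`, `GA_dom`, `TC_seq`, `TC_dom`, `NC_seq`, `NC_dom`.
#' @export
curate_markers <- function(hits, tree, evalue_max = 1e-3) {
  hits <- as.data.table(hits)
  stopifnot(all(c("model_id", "taxid", "full_score") %in% names(hits)))
  if ("evalue" %in% names(hits)) hits <- hits[evalue <= evalue_max]
  rows <- lapply(split(hits, by = "model_id", sorted = TRUE), function(h) {
    sel <- select_informative(h, tree)
    if (is.null(sel)) return(NULL)
    th <- derive_thresholds(sel$S1, sel$S2)
    data.table(model_id = h$model_id[[1L]], rank = sel$rank,
               taxon = sel$taxon, S1 = sel$S1, S2 = sel$S2,
               GA_seq = th$GA_seq, GA_dom = th$GA_dom,
               TC_seq = th$TC_seq, TC_dom = th$TC_dom,
               NC_seq = th$NC_seq, NC_dom = th$NC_dom)
  })
  out <- rbindlist(rows)
  if (!nrow(out))
    out <- data.table(model_id = character(), rank = character(),
                      taxon = character(), S1 = numeric(), S2 = numeric(),
                      GA_seq = numeric(), GA_dom = numeric(),
                      TC_seq = numeric(), TC_dom = numeric(),
                      NC_seq = numeric(), NC_dom = numeric())
  out[]
}

#' Read curation hits
#'
#' Either the simplified hits TSV (`model_id`, `seq_id`, `taxid`, `evalue`,
#' `full_score`) or a HMMER3 per-sequence table (`tblout` from hmmsearch,
#' where targets are sequences and queries are models) plus a
#' sequence-to-taxid mapping TSV (`seq_id`, `taxid`).
#'
#' @param path hits TSV or tblout file.
#' @param format `"tsv"` or `"tblout"`.
#' @param seq2taxid path to the mapping TSV (tblout only).
#' @return data.table with `model_id`, `seq_id`, `taxid`, `evalue`,
#'   `full_score`.
#' @export
read_curation_hits <- function(path, format = c("tsv", "tblout"),
                               seq2taxid = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    dt <- fread(path, sep = "\t", header = TRUE,
                colClasses = list(character = c("model_id", "seq_id", "taxid")))
    stopifnot(all(c("model_id", "seq_id", "taxid", "evalue", "full_score")
                  %in% names(dt)))
    return(dt)
  }
  if (is.null(seq2taxid))
    stop("tblout input needs a seq2taxid mapping TSV")
  tb <- .read_hmmer_table(path, min_fields = 18L)
  hits <- data.table(
    seq_id = vapply(tb, `[[`, character(1), 1L),
    model_id = vapply(tb, `[[`, character(1), 3L),
    evalue = as.numeric(vapply(tb, `[[`, character(1), 5L)),
    full_score = as.numeric(vapply(tb, `[[`, character(1), 6L))
  )
  map <- fread(seq2taxid, sep = "\t", header = TRUE, colClasses = "character")
  stopifnot(all(c("seq_id", "taxid") %in% names(map)))
  hits <- merge(hits, map[, .(seq_id, taxid)], by = "seq_id")
  hits[, .(model_id, seq_id, taxid, evalue, full_score)]
}

# split a HMMER3 whitespace table into fields, skipping '#' comment lines;
# errors carry the 1-based line number
.read_hmmer_table <- function(path, min_fields) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  parts <- strsplit(trimws(lines[keep]), "[ \t]+")
  short <- lengths(parts) < min_fields
  if (any(short))
    stop("malformed HMMER table row at line ", keep[which(short)[1L]],
         " of ", path, " (", lengths(parts)[which(short)[1L]],
         " fields, expected >= ", min_fields, ")")
  parts
}

#' Write / read the markers TSV
#'
#' @param markers data.table from [curate_markers()].
#' @param path file path.
#' @return `path` (write) or the markers data.table (read).
#' @export
write_markers_tsv <- function(markers, path) {
  fwrite(as.data.table(markers), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA",
        colClasses = list(character = c("model_id", "rank", "taxon")))
}
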