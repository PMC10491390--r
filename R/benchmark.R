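# Truth labelling from whole-genome alignment coordinates and
# precision/recall/F1 scoring of viral predictions.

#' Read a show-coords tab-delimited alignment table
#'
#' Expects the `show-coords -T` dialect: `S1 E1 S2 E2 LEN1 LEN2 %IDY REF
#' QRY` (reference coordinates first, then query/contig coordinates, which
#' may be reversed on the minus strand). Leading header/banner lines are
#' skipped. Query coordinates are normalized at parse time to 0-based
#' half-open forward intervals.
#'
#' @param path coords file.
#' @return data.table with `contig_id`, `ref_id`, `start`, `end`
#'   (0-based half-open on the contig), `identity` (percent).
#' @export
read_coords <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- strsplit(trimws(lines), "[ \t]+")
  ok <- vapply(rows, function(p)
    length(p) >= 9L && !is.na(suppressWarnings(as.numeric(p[[1L]]))),
    logical(1))
  rows <- rows[ok]
  if (!length(rows))
    return(data.table(contig_id = character(), ref_id = character(),
                      start = numeric(), end = numeric(),
                      identity = numeric()))
  s2 <- as.numeric(vapply(rows, `[[`, character(1), 3L))
  e2 <- as.numeric(vapply(rows, `[[`, character(1), 4L))
  data.table(
    contig_id = vapply(rows, `[[`, character(1), 9L),
    ref_id = vapply(rows, `[[`, character(1), 8L),
    start = pmin(s2, e2) - 1,
    end = pmax(s2, e2),
    identity = as.numeric(vapply(rows, `[[`, character(1), 7L))
  )
}

#' Truth-label contigs from genome alignments
#'
#' A contig is truly viral when the union of its alignment intervals at
#' identity >= `min_identity` covers at least `min_coverage` of its length
#' (both boundaries inclusive). Contigs without a qualifying alignment are
#' non-viral. `mode = "best"` replaces the merged union by the single
#' longest qualifying alignment.
#'
#' @param alignments table from [read_coords()] (0-based half-open
#'   `start`/`end` on the contig).
#' @param contig_lengths named numeric vector over every evaluated contig.
#' @param min_coverage minimum covered fraction (default 0.70).
#' @param min_identity minimum percent identity (default 90).
#' @param mode `"union"` (default) or `"best"`.
#' @return data.table with `contig_id`, `covered_frac`, `label`
#'   (`"viral"`/`"non-viral"`), one row per contig in `contig_lengths`.
#' @export
truth_labels <- function(alignments, contig_lengths, min_coverage = 0.70,
                         min_identity = 90, mode = c("union", "best")) {
  mode <- match.arg(mode)
  aln <- as.data.table(alignments)
  missing <- setdiff(unique(aln$contig_id), names(contig_lengths))
  if (length(missing))
    stop("aligned contig(s) absent from the lengths map: ",
         paste(missing, collapse = ", "))
  if (nrow(aln)) {
    if (any(aln$start < 0) ||
        any(aln$end > contig_lengths[aln$contig_id] + 1e-9))
      stop("alignment coordinates outside contig bounds")
  }
  qual <- aln[identity >= min_identity]
  cov <- vapply(names(contig_lengths), function(cid) {
    a <- qual[contig_id == cid]
    if (!nrow(a)) return(0)
    if (mode == "union") {
      ir <- IRanges::reduce(IRanges::IRanges(start = a$start + 1,
                                             end = a$end))
      sum(IRanges::width(ir))
    } else {
      max(a$end - a$start)
    }
  }, numeric(1)) / contig_lengths
  data.table(contig_id = names(contig_lengths),
             covered_frac = unname(cov),
             label = ifelse(cov >= min_coverage, "viral", "non-viral"))
}

#' Confusion counts over an evaluated contig set
#'
#' @param predicted_viral character vector of contig ids predicted viral
#'   (a putative-prophage call counts its host contig).
#' @param truth table from [truth_labels()] (or any data.frame with
#'   `contig_id`, `label`).
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(predicted_viral, truth) {
  tr <- as.data.table(truth)
  outside <- setdiff(predicted_viral, tr$contig_id)
  if (length(outside))
    stop("predicted id(s) outside the evaluated set: ",
         paste(outside, collapse = ", "))
  pred <- tr$contig_id %in% predicted_viral
  vir <- tr$label == "viral"
  list(tp = sum(pred & vir), fp = sum(pred & !vir),
       tn = sum(!pred & !vir), fn = sum(!pred & vir))
}

#' Precision, recall and F1 from confusion counts
#'
#' Undefined quantities (zero denominators) are reported as `NA`.
#'
#' @param counts list/row with `tp`, `fp`, `tn`, `fn`.
#' @return list with `precision`, `recall`, `f1`.
#' @export
metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  list(precision = precision, recall = recall, f1 = f1)
}

#' Run the benchmarking step on files
#'
#' @param coords show-coords table path.
#' @param contig_lengths named vector, or a FASTA path, or a lengths TSV
#'   (`contig_id`, `length`).
#' @param predictions triage assignments TSV (or data.table); every
#'   verdict other than `excluded` counts as predicted viral.
#' @param min_coverage,min_identity,mode see [truth_labels()].
#' @param out_dir optional output directory for truth/confusion/metrics
#'   TSVs.
#' @return list with `truth`, `counts`, `metrics`.
#' @export
run_benchmark <- function(coords, contig_lengths, predictions,
                          min_coverage = 0.70, min_identity = 90,
                          mode = "union", out_dir = NULL) {
  if (is.character(contig_lengths) && length(contig_lengths) == 1L) {
    if (grepl("\\.(fa|fasta|fna)$", contig_lengths)) {
      sq <- Biostrings::readDNAStringSet(contig_lengths)
      contig_lengths <- stats::setNames(BiocGenerics::width(sq),
                                        sub("\\s.*$", "", names(sq)))
    } else {
      lt <- fread(contig_lengths, sep = "\t", header = TRUE)
      contig_lengths <- stats::setNames(as.numeric(lt$length),
                                        as.character(lt$contig_id))
    }
  }
  if (is.character(coords)) coords <- read_coords(coords)
  if (is.character(predictions)) predictions <- fread(predictions, sep = "\t")
  pred <- as.data.table(predictions)
  predicted <- intersect(pred[verdict != "excluded", contig_id],
                         names(contig_lengths))
  truth <- truth_labels(coords, contig_lengths, min_coverage, min_identity,
                        mode = mode)
  counts <- confusion(predicted, truth)
  mt <- metrics(counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite(truth, file.path(out_dir, "truth_labels.tsv"), sep = "\t")
    fwrite(as.data.table(counts), file.path(out_dir, "confusion.tsv"),
           sep = "\t")
    fwrite(as.data.table(mt), file.path(out_dir, "metrics.tsv"), sep = "\t")
  }
  list(truth = truth, counts = counts, metrics = mt)
}
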