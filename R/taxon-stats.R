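# Per-taxon CDS statistics, descendant-aggregated marker counts and the
# taxon-specific ratio (TSR) that scales the voting threshold.

#' Per-taxon CDS count statistics
#'
#' Every assembly contributes its CDS count to each ancestor taxon at the
#' four working ranks present in its lineage. Assemblies with a CDS count
#' of zero (unannotated) are excluded; assemblies with a taxid absent from
#' the tree are skipped with a warning and tallied in the `rejects`
#' attribute. The standard deviation is the sample (n-1) form, defined as
#' zero for single-assembly taxa.
#'
#' @param records data.frame with `assembly_id`, `taxid`, `cds_count`.
#' @param tree a `taxonomy_tree`.
#' @return data.table with `taxon`, `rank`, `mean_cds`, `sd_cds`,
#'   `n_assemblies`; attribute `rejects` holds skipped assembly ids.
#' @export
cds_stats <- function(records, tree) {
  rec <- as.data.table(records)
  stopifnot(all(c("assembly_id", "taxid", "cds_count") %in% names(rec)))
  rec[, taxid := as.character(taxid)]
  rec <- rec[cds_count > 0]
  bad <- rec[!taxid %in% tree$taxid]
  if (nrow(bad)) {
    warning(nrow(bad), " assembly record(s) with unknown taxid skipped")
    rec <- rec[taxid %in% tree$taxid]
  }
  empty <- data.table(taxon = character(), rank = character(),
                      mean_cds = numeric(), sd_cds = numeric(),
                      n_assemblies = integer())
  if (!nrow(rec)) {
    setattr(empty, "rejects", bad$assembly_id)
    return(empty)
  }
  lin <- lineage_table(tree, unique(rec$taxid))
  long <- melt(merge(rec, lin, by = "taxid"),
               id.vars = c("assembly_id", "cds_count"),
               measure.vars = WORK_RANKS,
               variable.name = "rank", value.name = "taxon",
               variable.factor = FALSE)
  long <- long[!is.na(taxon)]
  if (!nrow(long)) {
    setattr(empty, "rejects", bad$assembly_id)
    return(empty)
  }
  out <- long[, .(
    mean_cds = mean(cds_count),
    sd_cds = if (.N > 1L) stats::sd(cds_count) else 0,
    n_assemblies = .N
  ), by = .(taxon, rank)]
  setorder(out, rank, taxon)
  setattr(out, "rejects", bad$assembly_id)
  out[]
}

#' Informative-marker counts per taxon, aggregated over descendants
#'
#' A genus's count is the number of markers directly targeting it. For
#' subfamily, family and order taxa the count additionally includes every
#' marker linked to any descendant taxon.
#'
#' @param markers markers table (needs `model_id`, `taxon`).
#' @param tree a `taxonomy_tree`.
#' @return data.table with `taxon`, `n_markers` (taxa with zero markers are
#'   omitted).
#' @export
marker_counts <- function(markers, tree) {
  mk <- as.data.table(markers)
  if (!nrow(mk)) return(data.table(taxon = character(), n_markers = integer()))
  .check_taxid(tree, mk$taxon)
  direct <- mk[, .(n_direct = .N), by = .(taxon = as.character(taxon))]
  # candidate taxa: anything carrying a marker, plus supra-genus ancestors
  lin <- lineage_table(tree, direct$taxon)
  cand <- unique(c(direct$taxon,
                   stats::na.omit(unlist(lin[, WORK_RANKS, with = FALSE]))))
  rows <- lapply(cand, function(t) {
    n <- direct[taxon == t, sum(n_direct)]
    if (tree$rank[[t]] %in% c("subfamily", "family", "order")) {
      desc <- descendants(tree, t)
      n <- n + direct[taxon %in% desc, sum(n_direct)]
    }
    data.table(taxon = t, n_markers = as.integer(n))
  })
  out <- rbindlist(rows)[n_markers > 0L]
  setorder(out, taxon)
  out[]
}

#' Taxon-specific ratio
#'
#' The ratio between a taxon's informative-marker count and its average CDS
#' count, capped at 1 when markers outnumber the average CDS. Undefined
#' (`NA`) when the marker count is zero or the mean CDS is non-positive;
#' such taxa are handled at voting time.
#'
#' @param n_markers integer vector of marker counts.
#' @param mean_cds numeric vector of average CDS counts.
#' @return numeric vector in (0, 1], with `NA` where undefined.
#' @export
tsr <- function(n_markers, mean_cds) {
  out <- ifelse(n_markers >= 1 & mean_cds > 0,
                pmin(1, n_markers / mean_cds), NA_real_)
  as.numeric(out)
}

#' Full per-taxon statistics table
#'
#' Joins [cds_stats()] and [marker_counts()] and computes the TSR per taxon.
#'
#' @param records assembly records (see [cds_stats()]).
#' @param markers markers table (see [marker_counts()]).
#' @param tree a `taxonomy_tree`.
#' @return data.table with `taxon`, `rank`, `mean_cds`, `sd_cds`,
#'   `n_assemblies`, `n_markers`, `tsr`.
#' @export
compute_taxon_stats <- function(records, markers, tree) {
  cs <- cds_stats(records, tree)
  mc <- marker_counts(markers, tree)
  out <- merge(cs, mc, by = "taxon", all = TRUE)
  out[is.na(n_markers), n_markers := 0L]
  out[is.na(rank), rank := unname(tree$rank[taxon])]
  out[, tsr := tsr(n_markers, mean_cds)]
  setorder(out, rank, taxon)
  out[]
}

#' Write / read the taxon-stats TSV
#'
#' @param stats data.table from [compute_taxon_stats()].
#' @param path file path.
#' @export
write_stats_tsv <- function(stats, path) {
  fwrite(as.data.table(stats), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname write_stats_tsv
#' @export
read_stats_tsv <- function(path) {
  fread(path, sep = "\t", header = TRUE, na.strings = "NA",
        colClasses = list(character = c("taxon", "rank")))
}

#' Per-rank taxonomy coverage counts
#'
#' How many taxa at each working rank carry at least one marker, next to
#' the number of taxa of that rank present in the tree.
#'
#' @param markers markers table.
#' @param tree a `taxonomy_tree`.
#' @return data.table with `rank`, `n_covered`, `n_total`, `coverage`.
#' @export
rank_coverage <- function(markers, tree) {
  mc <- marker_counts(markers, tree)
  rows <- lapply(WORK_RANKS, function(r) {
    all_r <- tree$taxid[tree$rank == r]
    cov <- sum(all_r %in% mc$taxon)
    data.table(rank = r, n_covered = cov, n_total = length(all_r),
               coverage = if (length(all_r)) cov / length(all_r) else NA_real_)
  })
  rbindlist(rows)
}
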