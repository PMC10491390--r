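# Gating of homology hits against calibrated marker thresholds and the
# rank-escalating taxonomic voting classifier.

#' Parse a HMMER3 per-domain table (domtblout)
#'
#' Extracts, for each domain row: model id (column 1), query CDS id
#' (column 4), full-sequence E-value (column 7), full-sequence score
#' (column 8) and the per-domain score (column 14). Multiple domain rows
#' for one (model, query) pair collapse to the best domain score. Comment
#' lines (`#`) are skipped; a short row is a parse error carrying its line
#' number.
#'
#' @param path a domtblout file.
#' @return data.table with `model_id`, `cds_id`, `full_evalue`,
#'   `full_score`, `dom_score`.
#' @export
parse_domain_table <- function(path) {
  parts <- .read_hmmer_table(path, min_fields = 22L)
  if (!length(parts))
    return(data.table(model_id = character(), cds_id = character(),
                      full_evalue = numeric(), full_score = numeric(),
                      dom_score = numeric()))
  dt <- data.table(
    model_id = vapply(parts, `[[`, character(1), 1L),
    cds_id = vapply(parts, `[[`, character(1), 4L),
    full_evalue = as.numeric(vapply(parts, `[[`, character(1), 7L)),
    full_score = as.numeric(vapply(parts, `[[`, character(1), 8L)),
    dom_score = as.numeric(vapply(parts, `[[`, character(1), 14L))
  )
  dt[, .(full_evalue = full_evalue[[1L]], full_score = full_score[[1L]],
         dom_score = max(dom_score)),
     by = .(model_id, cds_id)]
}

#' Gate hits against calibrated thresholds
#'
#' Hits to calibrated models are retained when the full-sequence score
#' reaches `GA_seq` and the best domain score reaches `GA_dom`
#' (confidence `"high"`, mirroring hmmscan's `--cut_ga`). Hits to known
#' but uncalibrated models (markers rows with `NA` thresholds, or ids in
#' `all_models`) fall back to the full-sequence E-value filter
#' (`<= evalue_max`, confidence `"low"`). Hits to models in neither set
#' are dropped.
#'
#' @param hits data.table from [parse_domain_table()].
#' @param markers markers table; rows with `NA` `GA_seq` count as
#'   uncalibrated but still carry their taxon into voting.
#' @param all_models optional character vector of additional model ids to
#'   treat as uncalibrated (no taxon); hits to them survive the E-value
#'   gate but cannot vote.
#' @param evalue_max fallback E-value cutoff (default 1e-3).
#' @return retained hits with added `confidence`, `taxon`, `rank` columns
#'   (`NA` taxon for models outside the markers table).
#' @export
gate_hits <- function(hits, markers, all_models = NULL, evalue_max = 1e-3) {
  hits <- as.data.table(hits)
  mk <- as.data.table(markers)
  out <- merge(hits, mk[, .(model_id, taxon, rank, GA_seq, GA_dom)],
               by = "model_id", all.x = TRUE)
  calibrated <- !is.na(out$GA_seq)
  known <- out$model_id %in% mk$model_id |
    out$model_id %in% (all_models %||% character(0))
  keep_high <- calibrated & out$full_score >= out$GA_seq &
    out$dom_score >= out$GA_dom
  keep_low <- !calibrated & known & out$full_evalue <= evalue_max
  out[, confidence := ifelse(keep_high, "high", "low")]
  out <- out[keep_high | keep_low]
  out[, c("GA_seq", "GA_dom") := NULL]
  out[]
}

#' Collapse to the best hit per CDS
#'
#' Per CDS the single hit with the highest full-sequence score is kept
#' (ties: higher domain score, then lexicographically smaller model id).
#' The contig id is the CDS id minus its final underscore-delimited token
#' (the `contigID_ordinal` gene-caller convention); CDS ids without an
#' underscore are routed to the `orphans` attribute.
#'
#' @param hits gated hits from [gate_hits()].
#' @return one row per CDS with an added `contig_id` column; attribute
#'   `orphans` lists unparseable CDS ids.
#' @export
best_hit_per_cds <- function(hits) {
  hits <- as.data.table(hits)
  if (!nrow(hits)) {
    out <- copy(hits)[, contig_id := character(0)]
    setattr(out, "orphans", character(0))
    return(out)
  }
  setorder(hits, cds_id, -full_score, -dom_score, model_id)
  out <- hits[, .SD[1L], by = cds_id]
  orphan <- !grepl("_", out$cds_id)
  out[, contig_id := sub("_[^_]*$", "", cds_id)]
  orphans <- out$cds_id[orphan]
  out <- out[!orphan]
  setattr(out, "orphans", orphans)
  out[]
}

#' Rank-escalating taxonomic vote for one contig
#'
#' Starting at the genus rank, every retained informative hit supports the
#' ancestor of its marker taxon at the current rank (hits whose marker
#' lineage lacks that rank support no candidate but stay in the
#' denominator). Candidates are iterated by descending proportion of hits
#' (ties: higher TSR, then lexicographically smaller id) and the first one
#' satisfying both voting conditions is accepted:
#' \enumerate{
#'   \item proportion >= `factor` x TSR(candidate);
#'   \item CDS_contig <= mean_cds + 2 * sd_cds for the candidate.
#' }
#' Candidates without statistics get TSR = 1 and the CDS condition waived
#' (with a warning). If no candidate is accepted the vote escalates to the
#' next rank; exhausting subfamily, family and order leaves the contig
#' unclassified.
#'
#' @param hits the contig's deduplicated informative hits (`taxon`,
#'   `rank`, `confidence`; rows with `NA` taxon are ignored).
#' @param n_cds total number of CDS called on the contig.
#' @param stats taxon-stats table (needs `taxon`, `mean_cds`, `sd_cds`,
#'   `tsr`).
#' @param tree a `taxonomy_tree`.
#' @param factor voting proportion factor (default 0.6).
#' @param rank_order ranks tried, finest first.
#' @return list: `outcome` ("classified"/"unclassified"), `deciding_rank`,
#'   `taxon`, `proportion`, `n_hits`, `n_hits_high`, `n_hits_low`,
#'   `lineage` (from the deciding rank upward, named by rank).
#' @export
vote <- function(hits, n_cds, stats, tree, factor = 0.6,
                 rank_order = WORK_RANKS) {
  hits <- as.data.table(hits)
  hits <- hits[!is.na(taxon)]
  unclassified <- list(outcome = "unclassified", deciding_rank = NA_character_,
                       taxon = NA_character_, proportion = NA_real_,
                       n_hits = nrow(hits),
                       n_hits_high = sum(hits$confidence == "high"),
                       n_hits_low = sum(hits$confidence == "low"),
                       lineage = NULL)
  if (!nrow(hits)) return(unclassified)
  st <- as.data.table(stats)
  n_total <- nrow(hits)
  lin <- lineage_table(tree, unique(hits$taxon))

  for (r in rank_order) {
    cand_of_hit <- lin[[r]][match(hits$taxon, lin$taxid)]
    tab <- table(cand_of_hit[!is.na(cand_of_hit)])
    if (!length(tab)) next
    cand <- data.table(taxon = names(tab),
                       proportion = as.numeric(tab) / n_total)
    cand <- merge(cand, st[, .(taxon, mean_cds, sd_cds, tsr)],
                  by = "taxon", all.x = TRUE)
    missing <- is.na(cand$tsr)
    if (any(missing))
      warning("no taxon statistics for ",
              paste(cand$taxon[missing], collapse = ", "),
              "; TSR set to 1 and CDS condition waived")
    cand[, tsr_used := ifelse(missing, 1, tsr)]
    setorder(cand, -proportion, -tsr_used, taxon)
    for (i in seq_len(nrow(cand))) {
      cond1 <- cand$proportion[[i]] >= factor * cand$tsr_used[[i]]
      cond2 <- is.na(cand$mean_cds[[i]]) ||
        n_cds <= cand$mean_cds[[i]] + 2 * cand$sd_cds[[i]]
      if (cond1 && cond2) {
        win <- cand$taxon[[i]]
        full <- lineage_of(tree, win)
        keep <- rank_order[seq(match(r, rank_order), length(rank_order))]
        lineage <- unlist(full[keep])
        return(list(outcome = "classified", deciding_rank = r,
                    taxon = win, proportion = cand$proportion[[i]],
                    n_hits = n_total,
                    n_hits_high = sum(hits$confidence == "high"),
                    n_hits_low = sum(hits$confidence == "low"),
                    lineage = lineage))
      }
    }
  }
  unclassified
}

#' Count CDS per contig
#'
#' From a GFF3 of gene calls (`type == "CDS"`, counted per seqid) or a
#' protein FASTA whose record ids follow the `contigID_ordinal` convention.
#'
#' @param path GFF3 or protein FASTA file.
#' @param format `"gff3"` or `"faa"`.
#' @return named integer vector, contig id -> CDS count.
#' @export
count_cds <- function(path, format = c("gff3", "faa")) {
  format <- match.arg(format)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[gr$type == "CDS"]
    tab <- table(as.character(GenomicRanges::seqnames(gr)))
  } else {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    tab <- table(sub("_[^_]*$", "", ids))
  }
  stats::setNames(as.integer(tab), names(tab))
}

#' Classify every contig in a domain table
#'
#' The full classification step: parse the domain table, gate against the
#' calibrated thresholds, collapse to one hit per CDS, group by contig and
#' run the taxonomic vote.
#'
#' @param domtbl domtblout path or a pre-parsed hits table.
#' @param markers markers table (or TSV path).
#' @param stats taxon-stats table (or TSV path).
#' @param tree a `taxonomy_tree` (or lineage TSV path).
#' @param cds_counts named vector from [count_cds()], or a GFF3/protein
#'   FASTA path. Contigs with hits but no CDS entry fall back to the
#'   number of distinct CDS with hits.
#' @param factor voting factor (default 0.6).
#' @param all_models see [gate_hits()].
#' @return data.table, one row per contig: `contig_id`, `outcome`,
#'   `deciding_rank`, `taxon`, `lineage` (semicolon-joined names from
#'   order down to the deciding rank), `proportion`, `n_hits_high`,
#'   `n_hits_low`, `n_cds`.
#' @export
classify_contigs <- function(domtbl, markers, stats, tree, cds_counts = NULL,
                             factor = 0.6, all_models = NULL) {
  if (is.character(domtbl)) domtbl <- parse_domain_table(domtbl)
  if (is.character(markers)) markers <- read_markers_tsv(markers)
  if (is.character(stats)) stats <- read_stats_tsv(stats)
  if (is.character(tree)) tree <- load_taxonomy(tree, "lineage-tsv")
  if (is.character(cds_counts)) {
    fmt <- if (grepl("\\.gff3?$", cds_counts)) "gff3" else "faa"
    cds_counts <- count_cds(cds_counts, fmt)
  }
  gated <- gate_hits(domtbl, markers, all_models = all_models)
  dedup <- best_hit_per_cds(gated)
  contigs <- union(names(cds_counts %||% integer(0)), unique(dedup$contig_id))
  rows <- lapply(sort(contigs), function(cid) {
    h <- dedup[contig_id == cid]
    n_cds <- if (!is.null(cds_counts) && cid %in% names(cds_counts))
      cds_counts[[cid]] else length(unique(h$cds_id))
    v <- vote(h, n_cds, stats, tree, factor = factor)
    # coarse-to-fine names, order first
    lineage_str <- if (is.null(v$lineage)) NA_character_ else
      paste(unname(tree$name[stats::na.omit(rev(v$lineage))]),
            collapse = ";")
    data.table(contig_id = cid, outcome = v$outcome,
               deciding_rank = v$deciding_rank, taxon = v$taxon,
               lineage = lineage_str, proportion = v$proportion,
               n_hits_high = v$n_hits_high, n_hits_low = v$n_hits_low,
               n_cds = as.integer(n_cds))
  })
  rbindlist(rows)
}

#' Krona-compatible text export of classifications
#'
#' One line per distinct lineage: a count, then TAB-separated taxon names
#' from the coarsest assigned rank down to the deciding rank. Unclassified
#' contigs appear as a single `unclassified` line.
#'
#' @param classifications table from [classify_contigs()].
#' @param tree a `taxonomy_tree`.
#' @param path optional output file.
#' @return character vector of Krona lines.
#' @export
krona_text <- function(classifications, tree, path = NULL) {
  cl <- as.data.table(classifications)
  key <- ifelse(cl$outcome == "classified",
                vapply(seq_len(nrow(cl)), function(i) {
                  l <- lineage_of(tree, cl$taxon[[i]])
                  ids <- rev(unlist(l[WORK_RANKS]))   # order -> genus
                  paste(unname(tree$name[stats::na.omit(ids)]),
                        collapse = "\t")
                }, character(1)),
                "unclassified")
  tab <- sort(table(key), decreasing = TRUE)
  lines <- sprintf("%d\t%s", as.integer(tab), names(tab))
  if (!is.null(path)) writeLines(lines, path)
  lines
}

#' Per-CDS annotation table
#'
#' The deduplicated, gated hits with contig ids — one row per annotated
#' CDS, suitable for downstream genome-map style reporting.
#'
#' @inheritParams classify_contigs
#' @return data.table with `contig_id`, `cds_id`, `model_id`, `taxon`,
#'   `rank`, `confidence`, `full_score`, `dom_score`, `full_evalue`.
#' @export
annotate_cds <- function(domtbl, markers, all_models = NULL) {
  if (is.character(domtbl)) domtbl <- parse_domain_table(domtbl)
  if (is.character(markers)) markers <- read_markers_tsv(markers)
  dedup <- best_hit_per_cds(gate_hits(domtbl, markers,
                                      all_models = all_models))
  setcolorder(dedup, c("contig_id", "cds_id", "model_id", "taxon", "rank",
                       "confidence", "full_score", "dom_score",
                       "full_evalue"))
  dedup[]
}
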