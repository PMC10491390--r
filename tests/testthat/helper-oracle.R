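# Independent brute-force oracles, written with naive loops over the plain
# node table so they share no code path with the implementation.

oracle_node_table <- function(tree) as.data.frame(tree)

oracle_ancestor_at_rank <- function(tree, id, r) {
  df <- oracle_node_table(tree)
  repeat {
    row <- df[df$taxid == id, ]
    if (row$rank == r) return(id)
    if (id == tree$root) return(NA_character_)
    id <- row$parent_taxid
  }
}

oracle_descendants <- function(tree, taxon) {
  df <- oracle_node_table(tree)
  out <- character(0)
  for (id in df$taxid) {
    if (id == taxon) next
    anc <- id
    repeat {
      if (anc == tree$root) break
      anc <- df$parent_taxid[df$taxid == anc]
      if (anc == taxon) { out <- c(out, id); break }
    }
  }
  sort(out)
}

# literal re-implementation of the informative-model selection: per-taxid
# best scores, per-rank grouping, single-taxon or non-overlap conditions
oracle_select_informative <- function(hits, tree) {
  best_by_taxid <- tapply(hits$full_score, hits$taxid, max)
  for (r in c("genus", "subfamily", "family", "order")) {
    groups <- list()
    for (t in names(best_by_taxid)) {
      anc <- oracle_ancestor_at_rank(tree, t, r)
      if (is.na(anc)) next
      groups[[anc]] <- c(groups[[anc]], best_by_taxid[[t]])
    }
    if (!length(groups)) next
    lows <- vapply(groups, min, numeric(1))
    highs <- vapply(groups, max, numeric(1))
    ord <- order(-highs, -lows, names(groups))
    best <- names(groups)[ord[1L]]
    others <- setdiff(names(groups), best)
    if (!length(others))
      return(list(rank = r, taxon = best, S1 = lows[[best]], S2 = NA_real_))
    if (lows[[best]] > max(highs[others]))
      return(list(rank = r, taxon = best, S1 = lows[[best]],
                  S2 = max(highs[others])))
  }
  NULL
}

# literal re-implementation of the two voting conditions with rank
# escalation; hits is a data.frame with a `taxon` column
oracle_vote <- function(hits, n_cds, stats, tree, factor = 0.6) {
  taxa <- hits$taxon[!is.na(hits$taxon)]
  n_total <- length(taxa)
  if (!n_total) return(NULL)
  for (r in c("genus", "subfamily", "family", "order")) {
    cand <- character(0)
    for (t in taxa) {
      a <- oracle_ancestor_at_rank(tree, t, r)
      if (!is.na(a)) cand <- c(cand, a)
    }
    if (!length(cand)) next
    counts <- table(cand)
    cands <- names(counts)
    prop <- as.numeric(counts) / n_total
    tsr_used <- numeric(length(cands))
    mean_cds <- rep(NA_real_, length(cands))
    sd_cds <- rep(NA_real_, length(cands))
    for (i in seq_along(cands)) {
      row <- stats[stats$taxon == cands[[i]], ]
      if (nrow(row) == 1L && !is.na(row$tsr)) {
        tsr_used[[i]] <- row$tsr
        mean_cds[[i]] <- row$mean_cds
        sd_cds[[i]] <- row$sd_cds
      } else {
        tsr_used[[i]] <- 1
      }
    }
    for (i in order(-prop, -tsr_used, cands)) {
      cond1 <- prop[[i]] >= factor * tsr_used[[i]]
      cond2 <- is.na(mean_cds[[i]]) ||
        n_cds <= mean_cds[[i]] + 2 * sd_cds[[i]]
      if (cond1 && cond2)
        return(list(rank = r, taxon = cands[[i]], proportion = prop[[i]]))
    }
  }
  NULL
}
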