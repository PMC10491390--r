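# Deterministic, seeded generators for every input format the other
# modules consume, with planted ground truth. All randomness flows from
# the single seed in the fixture spec; the global RNG state is restored
# after each call.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic fixture bundle
#'
#' Collects every knob of the generators in one validated list. Defaults
#' describe a desk-scale world: a two-order taxonomy with eight genera,
#' three curated models per genus separated from off-target scores by at
#' least 1.5 bits, 100 contigs around one CDS per kb, 20% cross-genus hit
#' noise, and error-free predictor tables.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_orders,n_families,n_subfamilies,n_genera,taxids_per_genus
#'   balanced taxonomy shape (subfamilies may be 0).
#' @param models_per_genus curated marker models planted per genus.
#' @param n_models optional total model count overriding
#'   `models_per_genus * n_genera`; models are assigned to genera
#'   round-robin.
#' @param score_separation minimum bit-score gap between a planted model's
#'   target-taxon range and its off-target scores; per-model gaps are drawn
#'   in `[separation, separation + 8]` so the 3-bit trim guard of the
#'   threshold formula is exercised when `separation < 3`.
#' @param frac_noninformative fraction of models planted with overlapping
#'   cross-order score ranges (non-informative by construction); needs at
#'   least two orders.
#' @param n_contigs,viral_fraction contig set size and viral share.
#' @param cds_per_kb CDS density used to turn CDS counts into contig
#'   lengths (~1 gene/kb, phage-like).
#' @param hit_fraction fraction of a viral entity's CDS that carry marker
#'   hits.
#' @param noise cross-taxon hit fraction in `[0, 1]`: probability that a
#'   hit points at a marker of a different genus.
#' @param assemblies_per_taxid assemblies generated per leaf taxid.
#' @param verdict_probs named probabilities over the intended
#'   HC / LC / PP verdicts of viral contigs.
#' @param predictor_error named per-tool error rates (`virsorter`,
#'   `virfinder`, `pprmeta`): probability that a tool drops a true signal
#'   or, for non-viral contigs, emits a spurious one.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_orders = 2L, n_families = 4L, n_subfamilies = 2L,
                         n_genera = 8L, taxids_per_genus = 3L,
                         models_per_genus = 3L,
                         n_models = NULL,
                         score_separation = 1.5,
                         frac_noninformative = 0.1,
                         n_contigs = 100L, viral_fraction = 0.6,
                         cds_per_kb = 1,
                         hit_fraction = 0.6,
                         noise = 0.2,
                         assemblies_per_taxid = 3L,
                         verdict_probs = c(HC = 0.5, LC = 0.3, PP = 0.2),
                         predictor_error = c(virsorter = 0, virfinder = 0,
                                             pprmeta = 0)) {
  spec <- list(seed = as.integer(seed), n_orders = as.integer(n_orders),
               n_families = as.integer(n_families),
               n_subfamilies = as.integer(n_subfamilies),
               n_genera = as.integer(n_genera),
               taxids_per_genus = as.integer(taxids_per_genus),
               models_per_genus = as.integer(models_per_genus),
               n_models = if (!is.null(n_models)) as.integer(n_models),
               score_separation = score_separation,
               frac_noninformative = frac_noninformative,
               n_contigs = as.integer(n_contigs),
               viral_fraction = viral_fraction,
               cds_per_kb = cds_per_kb,
               hit_fraction = hit_fraction, noise = noise,
               assemblies_per_taxid = as.integer(assemblies_per_taxid),
               verdict_probs = verdict_probs,
               predictor_error = predictor_error)
  stopifnot(spec$n_orders >= 1L, spec$n_families >= 1L,
            spec$n_genera >= 1L, spec$taxids_per_genus >= 1L,
            spec$models_per_genus >= 1L,
            spec$score_separation > 0,
            spec$frac_noninformative >= 0, spec$frac_noninformative <= 1,
            spec$noise >= 0, spec$noise <= 1,
            spec$hit_fraction > 0, spec$hit_fraction <= 1,
            spec$viral_fraction >= 0, spec$viral_fraction <= 1,
            abs(sum(spec$verdict_probs) - 1) < 1e-9)
  structure(spec, class = "fixture_spec")
}

#' Generate a balanced synthetic taxonomy
#'
#' Families are distributed round-robin across orders, subfamilies across
#' families, genera across families (placed under a subfamily when their
#' family has one), and `taxids_per_genus` species leaves under each
#' genus. Ids are deterministic for a fixed shape.
#'
#' @param spec a [fixture_spec()].
#' @param out optional path; when given, the lineage TSV is written there.
#' @return a `taxonomy_tree`.
#' @export
make_taxonomy <- function(spec, out = NULL) {
  ords <- sprintf("ord%d", seq_len(spec$n_orders))
  fams <- sprintf("fam%d", seq_len(spec$n_families))
  subs <- if (spec$n_subfamilies > 0)
    sprintf("sub%d", seq_len(spec$n_subfamilies)) else character(0)
  gens <- sprintf("gen%d", seq_len(spec$n_genera))

  fam_parent <- ords[(seq_along(fams) - 1L) %% length(ords) + 1L]
  sub_parent <- fams[(seq_along(subs) - 1L) %% length(fams) + 1L]
  gen_fam <- fams[(seq_along(gens) - 1L) %% length(fams) + 1L]
  gen_parent <- vapply(seq_along(gens), function(g) {
    f <- gen_fam[[g]]
    cand <- subs[sub_parent == f]
    if (!length(cand)) return(f)
    # round-robin among the family's subfamilies
    prior <- sum(gen_fam[seq_len(g - 1L)] == f)
    cand[prior %% length(cand) + 1L]
  }, character(1))

  taxid <- c("root", ords, fams, subs, gens)
  name <- c("Viruses", sprintf("Order_%d", seq_along(ords)),
            sprintf("Family_%d", seq_along(fams)),
            sprintf("Subfamily_%d", seq_along(subs)),
            sprintf("Genus_%d", seq_along(gens)))
  rank <- c("no-rank", rep("order", length(ords)),
            rep("family", length(fams)), rep("subfamily", length(subs)),
            rep("genus", length(gens)))
  parent <- c("root", rep("root", length(ords)), fam_parent, sub_parent,
              gen_parent)
  for (g in seq_along(gens)) {
    sp <- sprintf("t%d_%d", g, seq_len(spec$taxids_per_genus))
    taxid <- c(taxid, sp)
    name <- c(name, sprintf("Species_%d_%d", g, seq_len(spec$taxids_per_genus)))
    rank <- c(rank, rep("species", length(sp)))
    parent <- c(parent, rep(gens[[g]], length(sp)))
  }
  tree <- taxonomy_tree(taxid, name, rank, parent)
  if (!is.null(out)) write_lineage_tsv(tree, out)
  tree
}

#' Generate a curation hits table with planted informative models
#'
#' Each planted informative model targets one genus: its per-taxid best
#' scores within the target genus all sit at least the model's gap above
#' the maximum off-target score, so S1 and S2 are known by construction.
#' A `frac_noninformative` share of models is planted with overlapping
#' score ranges across two genera from different orders (unplantable, with
#' a warning, when the taxonomy has a single order). Extra sub-best hits
#' per taxid and decoy hits to an unknown model id exercise the per-taxid
#' maximum and downstream gating.
#'
#' @param tree taxonomy from [make_taxonomy()].
#' @param spec a [fixture_spec()].
#' @param out_dir optional directory for `curation_hits.tsv` and
#'   `model_truth.tsv`.
#' @return list with `hits` (model_id, seq_id, taxid, evalue, full_score)
#'   and `truth` (model_id, informative, rank, taxon, S1, S2).
#' @export
make_curation_hits <- function(tree, spec, out_dir = NULL) {
  .with_seed(spec$seed + 101L, {
    gens <- tree$taxid[tree$rank == "genus"]
    gen_order <- vapply(gens, function(g) lineage_of(tree, g)$order,
                        character(1))
    taxids_of <- lapply(gens, function(g)
      descendants(tree, g))
    names(taxids_of) <- gens

    n_models <- spec$n_models %||% (spec$models_per_genus * length(gens))
    n_noninf <- round(spec$frac_noninformative * n_models)
    if (n_noninf > 0 && length(unique(gen_order)) < 2L) {
      warning("non-informative planting needs >= 2 orders; skipped")
      n_noninf <- 0L
    }
    model_ids <- sprintf("VMRK%05d", seq_len(n_models))
    noninf_idx <- if (n_noninf > 0)
      sort(sample(n_models, n_noninf)) else integer(0)

    hit_rows <- list()
    truth_rows <- list()
    seq_n <- 0L
    emit <- function(model, taxid, best) {
      # the per-taxid best plus 0-2 lower-scoring sequences
      n_extra <- sample(0:2, 1L)
      scores <- c(best, best - runif(n_extra, 1, 15))
      scores <- pmax(scores, 5)
      seq_n <<- seq_n + length(scores)
      data.table(model_id = model,
                 seq_id = sprintf("seq%06d", seq_n - rev(seq_len(length(scores))) + 1L),
                 taxid = taxid,
                 evalue = 10^-runif(length(scores), 4, 40),
                 full_score = round(scores, 1))
    }

    g_cursor <- 0L
    for (mi in seq_len(n_models)) {
      model <- model_ids[[mi]]
      if (mi %in% noninf_idx) {
        # two genera from different orders with matching subfamily
        # presence, so every rank sees two overlapping ranges (a lone
        # subfamily taxon would otherwise make the model informative)
        has_sub <- vapply(gens, function(g)
          !is.na(lineage_of(tree, g)$subfamily), logical(1))
        pair <- NULL
        for (hs in unique(has_sub)) {
          cand <- gens[has_sub == hs]
          if (length(unique(gen_order[match(cand, gens)])) >= 2L) {
            o1 <- gen_order[match(cand, gens)][[1L]]
            pair <- c(sample(cand[gen_order[match(cand, gens)] == o1], 1L),
                      sample(cand[gen_order[match(cand, gens)] != o1], 1L))
            break
          }
        }
        if (is.null(pair)) {
          warning("no cross-order genus pair with matching subfamily ",
                  "presence; non-informative model ", model, " skipped")
          truth_rows[[length(truth_rows) + 1L]] <- data.table(
            model_id = model, informative = FALSE, rank = NA_character_,
            taxon = NA_character_, S1 = NA_real_, S2 = NA_real_)
          next
        }
        gA <- pair[[1L]]; gB <- pair[[2L]]
        tA <- taxids_of[[gA]]; tB <- taxids_of[[gB]]
        if (spec$taxids_per_genus == 1L) {
          bestA <- 60; bestB <- 60
        } else {
          bestA <- c(60, round(runif(length(tA) - 1L, 50, 60), 1))
          bestB <- c(55, 65, round(runif(max(0L, length(tB) - 2L), 55, 65), 1))
          bestB <- bestB[seq_along(tB)]
        }
        for (k in seq_along(tA))
          hit_rows[[length(hit_rows) + 1L]] <- emit(model, tA[[k]], bestA[[k]])
        for (k in seq_along(tB))
          hit_rows[[length(hit_rows) + 1L]] <- emit(model, tB[[k]], bestB[[k]])
        truth_rows[[length(truth_rows) + 1L]] <- data.table(
          model_id = model, informative = FALSE, rank = NA_character_,
          taxon = NA_character_, S1 = NA_real_, S2 = NA_real_)
        next
      }
      g_cursor <- g_cursor %% length(gens) + 1L
      g <- gens[[g_cursor]]
      others <- setdiff(gens, g)
      has_s2 <- length(others) > 0 && runif(1) < 0.875
      S2 <- NA_real_
      if (has_s2) {
        offg <- sample(others, sample(seq_len(min(3L, length(others))), 1L))
        off_bests <- numeric(0)
        for (og in offg) {
          tt <- taxids_of[[og]]
          tt <- tt[sample(length(tt), sample(length(tt), 1L))]
          for (t in tt) {
            b <- round(runif(1, 30, 60), 1)
            off_bests <- c(off_bests, b)
            hit_rows[[length(hit_rows) + 1L]] <- emit(model, t, b)
          }
        }
        S2 <- max(off_bests)
      }
      gap <- runif(1, spec$score_separation, spec$score_separation + 8)
      base <- if (has_s2) S2 else round(runif(1, 30, 60), 1)
      tt <- taxids_of[[g]]
      bests <- round(base + gap + runif(length(tt), 0, 12), 1)
      for (k in seq_along(tt))
        hit_rows[[length(hit_rows) + 1L]] <- emit(model, tt[[k]], bests[[k]])
      truth_rows[[length(truth_rows) + 1L]] <- data.table(
        model_id = model, informative = TRUE, rank = "genus", taxon = g,
        S1 = min(bests), S2 = S2)
    }

    hits <- rbindlist(hit_rows)
    truth <- rbindlist(truth_rows)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fwrite(hits, file.path(out_dir, "curation_hits.tsv"), sep = "\t")
      fwrite(truth, file.path(out_dir, "model_truth.tsv"), sep = "\t",
             na = "NA")
    }
    list(hits = hits, truth = truth)
  })
}

#' Generate a per-assembly CDS-count table
#'
#' Each genus gets a characteristic genome size (uniform 15-80 CDS) and
#' every leaf taxid contributes `assemblies_per_taxid` assemblies whose
#' CDS counts scatter around it (normal, CV ~ 12%, floor 5).
#'
#' @param tree taxonomy from [make_taxonomy()].
#' @param spec a [fixture_spec()].
#' @param out optional TSV path.
#' @return data.table with `assembly_id`, `taxid`, `cds_count`.
#' @export
make_assemblies <- function(tree, spec, out = NULL) {
  .with_seed(spec$seed + 202L, {
    gens <- tree$taxid[tree$rank == "genus"]
    rows <- list()
    for (g in gens) {
      mean_g <- round(runif(1, 15, 80))
      for (t in descendants(tree, g)) {
        n <- spec$assemblies_per_taxid
        cds <- pmax(5, round(stats::rnorm(n, mean_g, 0.12 * mean_g)))
        rows[[length(rows) + 1L]] <- data.table(
          assembly_id = sprintf("asm_%s_%d", t, seq_len(n)),
          taxid = t, cds_count = as.integer(cds))
      }
    }
    out_dt <- rbindlist(rows)
    if (!is.null(out)) fwrite(out_dt, out, sep = "\t")
    out_dt
  })
}

# random nucleotide sequence of length n
.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# write a genuine 23-column hmmscan domtblout (fixed layout) so the
# production parser is the one under test
.write_domtbl <- function(rows, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#                                                                            --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"
  ), con)
  for (i in seq_len(nrow(rows))) {
    r <- rows[i]
    writeLines(sprintf(
      "%-20s -          %5d %-20s -          %5d %9.2g %6.1f %5.1f %3d %3d %9.2g %9.2g %6.1f %5.1f %5d %5d %5d %5d %5d %5d %4.2f -",
      r$model_id, 120L, r$cds_id, r$qlen, r$full_evalue, r$full_score, 0.1,
      r$dom_i, r$dom_n, r$full_evalue, r$full_evalue * 2, r$dom_score, 0.1,
      1L, 100L, 5L, 104L, 1L, 110L, 0.95), con)
  }
  invisible(path)
}

#' Generate a full contig set with planted triage and taxonomy truth
#'
#' Emits, under `out_dir`: the contig FASTA, a GFF3 of CDS calls, a
#' hmmscan-layout domain table over the classification entities (HC/LC
#' contigs and excised prophage regions), VirSorter/VirFinder/PPR-Meta
#' tables derived from the intended verdicts with the spec's per-tool
#' error rates, a show-coords alignment table in which viral contigs are
#' covered >= 70% at >= 90% identity and non-viral contigs fall below
#' both gates, and the ground-truth TSV.
#'
#' Viral entities draw their CDS counts inside `mean + 2*sd` of their
#' source genus's realized statistics (so the planted lineage is
#' recoverable by the voting conditions), and their CDS carry hits to the
#' source genus's markers with the spec's cross-genus noise.
#'
#' @param tree taxonomy from [make_taxonomy()].
#' @param markers calibrated markers table (e.g. from [curate_markers()]
#'   on [make_curation_hits()] output).
#' @param stats taxon-stats table from [compute_taxon_stats()].
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created).
#' @return list with `truth` (per-contig table) and the emitted `paths`.
#' @export
make_contig_set <- function(tree, markers, stats, spec, out_dir) {
  .with_seed(spec$seed + 303L, {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    mk <- as.data.table(markers)
    st <- as.data.table(stats)
    gen_mk <- mk[rank == "genus"]
    gens <- intersect(unique(gen_mk$taxon), st$taxon)
    if (!length(gens)) stop("no genus has both markers and statistics")

    n_viral <- round(spec$n_contigs * spec$viral_fraction)
    n_non <- spec$n_contigs - n_viral
    verdicts <- sample(names(spec$verdict_probs), n_viral, replace = TRUE,
                       prob = spec$verdict_probs)
    src_gen <- gens[(seq_len(n_viral) - 1L) %% length(gens) + 1L]

    fa <- character(0)
    gff <- list()
    dom_rows <- list()
    vs_rows <- list(); vf_rows <- list(); pm_rows <- list()
    coords <- list()
    truth <- list()
    err <- spec$predictor_error

    draw_ncds <- function(g) {
      srow <- st[taxon == g]
      lo <- max(3, ceiling(srow$mean_cds - 2 * srow$sd_cds))
      hi <- max(lo, floor(srow$mean_cds + 2 * srow$sd_cds))
      lo + sample.int(hi - lo + 1L, 1L) - 1L
    }
    emit_hits <- function(entity, g, n_cds) {
      n_hits <- max(1L, round(spec$hit_fraction * n_cds))
      n_hits <- min(n_hits, n_cds)
      cds_pick <- sample(n_cds, n_hits)
      rows <- lapply(cds_pick, function(ci) {
        use_noise <- spec$noise > 0 && runif(1) < spec$noise &&
          nrow(gen_mk[taxon != g]) > 0L
        pool <- if (use_noise) gen_mk[taxon != g] else gen_mk[taxon == g]
        m <- pool[sample(nrow(pool), 1L)]
        full <- m$GA_seq + runif(1, 0.5, 15)
        dom <- m$GA_dom + runif(1) * (full - m$GA_dom)
        n_dom <- if (runif(1) < 0.2) 2L else 1L
        rbindlist(lapply(seq_len(n_dom), function(d) data.table(
          model_id = m$model_id,
          cds_id = sprintf("%s_%d", entity, ci),
          qlen = 200L,
          full_evalue = 10^-runif(1, 5, 30),
          full_score = round(full, 1),
          dom_score = round(if (d == n_dom) dom else dom - runif(1, 1, 5), 1),
          dom_i = d, dom_n = n_dom)))
      })
      rbindlist(rows)
    }
    emit_cds_gff <- function(entity, len, n_cds) {
      step <- len / n_cds
      data.table(
        seqid = entity,
        start = pmax(1L, as.integer(floor((seq_len(n_cds) - 1) * step)) + 1L),
        end = pmin(as.integer(len), as.integer(floor(seq_len(n_cds) * step))),
        id = sprintf("%s_%d", entity, seq_len(n_cds)))
    }

    for (i in seq_len(n_viral)) {
      cid <- sprintf("c%03d", i)
      g <- src_gen[[i]]
      v <- verdicts[[i]]
      n_cds <- draw_ncds(g)
      ent_len <- max(1500L, as.integer(round(n_cds / spec$cds_per_kb * 1000)))
      if (v == "PP") {
        a <- 1000L
        b <- a + ent_len
        len <- b + 1000L
        entity <- sprintf("%s|prophage-%d:%d", cid, a, b)
        region <- c(a, b)
      } else {
        len <- ent_len
        entity <- cid
        region <- NULL
      }
      fa[cid] <- .rand_dna(len)
      gff[[length(gff) + 1L]] <- emit_cds_gff(entity, ent_len, n_cds)
      dom_rows[[length(dom_rows) + 1L]] <- emit_hits(entity, g, n_cds)

      if (v == "HC") {
        if (runif(1) >= err[["virsorter"]])
          vs_rows[[length(vs_rows) + 1L]] <- data.table(
            contig_id = cid, category = sample(1:2, 1L),
            start = NA_integer_, end = NA_integer_)
      } else if (v == "PP") {
        if (runif(1) >= err[["virsorter"]])
          vs_rows[[length(vs_rows) + 1L]] <- data.table(
            contig_id = cid, category = sample(4:5, 1L),
            start = region[[1L]] + 1L, end = region[[2L]])
      } else {
        rule <- sample(1:3, 1L)
        vf_ok <- runif(1) >= err[["virfinder"]]
        if (rule == 1L && vf_ok) {
          vf_rows[[length(vf_rows) + 1L]] <- data.table(
            contig_id = cid, length = len,
            score = round(runif(1, 0.9, 0.99), 3),
            pvalue = round(runif(1, 0.001, 0.04), 4))
        } else if (rule == 2L) {
          if (vf_ok)
            vf_rows[[length(vf_rows) + 1L]] <- data.table(
              contig_id = cid, length = len,
              score = round(runif(1, 0.7, 0.89), 3),
              pvalue = round(runif(1, 0.001, 0.04), 4))
          if (runif(1) >= err[["virsorter"]])
            vs_rows[[length(vs_rows) + 1L]] <- data.table(
              contig_id = cid, category = 3L,
              start = NA_integer_, end = NA_integer_)
        } else if (vf_ok) {
          vf_rows[[length(vf_rows) + 1L]] <- data.table(
            contig_id = cid, length = len,
            score = round(runif(1, 0.7, 0.89), 3),
            pvalue = round(runif(1, 0.001, 0.04), 4))
          if (runif(1) >= err[["pprmeta"]])
            pm_rows[[length(pm_rows) + 1L]] <- data.table(
              Header = cid, Length = len, phage_score = 0.95,
              chromosome_score = 0.03, plasmid_score = 0.02,
              Possible_source = "phage")
        }
      }
      # qualifying alignment: single interval covering >= 70%
      frac <- runif(1, 0.75, 0.95)
      alen <- round(frac * len)
      a0 <- sample.int(len - alen + 1L, 1L) - 1L
      coords[[length(coords) + 1L]] <- data.table(
        s1 = 1L, e1 = alen, s2 = a0 + 1L, e2 = a0 + alen,
        len1 = alen, len2 = alen, idy = round(runif(1, 92, 99), 2),
        ref = paste0("ref_", g), qry = cid)
      truth[[length(truth) + 1L]] <- data.table(
        contig_id = cid, label = "viral", verdict = v, genus = g,
        entity_id = entity, n_cds = n_cds, length = len)
    }

    for (i in seq_len(n_non)) {
      cid <- sprintf("n%03d", i)
      len <- as.integer(round(runif(1, 2000, 40000)))
      fa[cid] <- .rand_dna(len)
      spurious <- runif(1) < err[["virfinder"]]
      if (spurious) {
        vf_rows[[length(vf_rows) + 1L]] <- data.table(
          contig_id = cid, length = len,
          score = round(runif(1, 0.9, 0.99), 3),
          pvalue = round(runif(1, 0.001, 0.04), 4))
      } else if (runif(1) < 0.5) {
        # benign, non-firing evidence
        vf_rows[[length(vf_rows) + 1L]] <- data.table(
          contig_id = cid, length = len,
          score = round(runif(1, 0.1, 0.6), 3),
          pvalue = round(runif(1, 0.2, 0.9), 4))
        pm_rows[[length(pm_rows) + 1L]] <- data.table(
          Header = cid, Length = len, phage_score = 0.05,
          chromosome_score = 0.9, plasmid_score = 0.05,
          Possible_source = "chromosome")
      }
      if (runif(1) < 0.5) {
        # sub-threshold alignment: short and low identity
        alen <- round(runif(1, 0.2, 0.6) * len)
        coords[[length(coords) + 1L]] <- data.table(
          s1 = 1L, e1 = alen, s2 = 1L, e2 = alen, len1 = alen, len2 = alen,
          idy = round(runif(1, 70, 85), 2), ref = "ref_host", qry = cid)
      }
      truth[[length(truth) + 1L]] <- data.table(
        contig_id = cid, label = "non-viral",
        verdict = if (spurious) "LC" else "excluded",
        genus = NA_character_, entity_id = NA_character_,
        n_cds = NA_integer_, length = len)
    }

    # decoy hits to a model unknown to the markers table (dropped by gating)
    if (length(dom_rows)) {
      dom_rows[[length(dom_rows) + 1L]] <- data.table(
        model_id = "VMRK99999", cds_id = paste0(truth[[1L]]$entity_id, "_1"),
        qlen = 200L, full_evalue = 1e-5, full_score = 45.0, dom_score = 44.0,
        dom_i = 1L, dom_n = 1L)
    }

    paths <- list(
      fasta = file.path(out_dir, "contigs.fasta"),
      gff3 = file.path(out_dir, "cds.gff3"),
      domtbl = file.path(out_dir, "scan.domtbl"),
      virsorter = file.path(out_dir, "virsorter.csv"),
      virfinder = file.path(out_dir, "virfinder.tsv"),
      pprmeta = file.path(out_dir, "pprmeta.csv"),
      coords = file.path(out_dir, "alignments.coords"),
      truth = file.path(out_dir, "contig_truth.tsv"))

    seqs <- Biostrings::DNAStringSet(fa)
    Biostrings::writeXStringSet(seqs, paths$fasta)

    gff_dt <- rbindlist(gff)
    gr <- GenomicRanges::GRanges(
      seqnames = gff_dt$seqid,
      ranges = IRanges::IRanges(start = gff_dt$start, end = gff_dt$end),
      strand = "+")
    gr$source <- "synthetic"
    gr$type <- "CDS"
    gr$phase <- 0L
    gr$ID <- gff_dt$id
    rtracklayer::export(gr, paths$gff3, format = "gff3")

    dom <- rbindlist(dom_rows)
    setorder(dom, cds_id, model_id, dom_i)
    .write_domtbl(dom, paths$domtbl)

    vs <- rbindlist(vs_rows)
    if (!nrow(vs)) vs <- data.table(contig_id = character(),
                                    category = integer(),
                                    start = integer(), end = integer())
    vf <- rbindlist(vf_rows)
    if (!nrow(vf)) vf <- data.table(contig_id = character(),
                                    length = integer(), score = numeric(),
                                    pvalue = numeric())
    pm <- rbindlist(pm_rows)
    if (!nrow(pm)) pm <- data.table(Header = character(), Length = integer(),
                                    phage_score = numeric(),
                                    chromosome_score = numeric(),
                                    plasmid_score = numeric(),
                                    Possible_source = character())
    fwrite(vs, paths$virsorter)
    fwrite(vf, paths$virfinder, sep = "\t")
    fwrite(pm, paths$pprmeta)
    co <- rbindlist(coords)
    fwrite(co, paths$coords, sep = "\t", col.names = FALSE)
    truth_dt <- rbindlist(truth)
    fwrite(truth_dt, paths$truth, sep = "\t", na = "NA")
    list(truth = truth_dt, paths = paths)
  })
}

#' Generate the complete fixture bundle
#'
#' Runs every generator under one seed and writes the full bundle plus
#' ground truth into `out_dir`: taxonomy, curation hits, calibrated
#' markers, assembly table, taxon stats, and the contig set.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory.
#' @return list with `tree`, `markers`, `stats`, `curation`, `assemblies`,
#'   `contigs` (the [make_contig_set()] result) and `paths`.
#' @export
generate_fixture_bundle <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tax_path <- file.path(out_dir, "taxonomy.tsv")
  tree <- make_taxonomy(spec, out = tax_path)
  cur <- make_curation_hits(tree, spec, out_dir = out_dir)
  markers <- curate_markers(cur$hits, tree)
  write_markers_tsv(markers, file.path(out_dir, "markers.tsv"))
  asm <- make_assemblies(tree, spec, out = file.path(out_dir, "assemblies.tsv"))
  stats <- compute_taxon_stats(asm, markers, tree)
  write_stats_tsv(stats, file.path(out_dir, "taxon_stats.tsv"))
  contigs <- make_contig_set(tree, markers, stats, spec, out_dir)
  list(tree = tree, markers = markers, stats = stats, curation = cur,
       assemblies = asm, contigs = contigs,
       paths = c(list(taxonomy = tax_path,
                      markers = file.path(out_dir, "markers.tsv"),
                      stats = file.path(out_dir, "taxon_stats.tsv"),
                      assemblies = file.path(out_dir, "assemblies.tsv")),
                 contigs$paths))
}
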