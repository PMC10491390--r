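# Evidence-based triage of contigs into high-confidence (HC),
# low-confidence (LC), putative-prophage (PP) or excluded sets.
#
# Region coordinates are 0-based half-open internally; predictor tables are
# read as 1-based inclusive and converted at the boundary.

#' Length-filter contigs
#'
#' Keeps contigs at least `min_length` bp long (boundary inclusive). The
#' default of 1.5 kb reflects that shorter viral contigs rarely encode
#' enough proteins for marker-based classification; virome-scale surveys
#' may raise this (e.g. 5 kb).
#'
#' @param contigs a [Biostrings::DNAStringSet] (or anything with
#'   `width()`/`names()`).
#' @param min_length minimum retained length in bp.
#' @return list with `kept` (the retained set) and `report`
#'   (`n_in`, `n_kept`, `n_dropped`).
#' @export
length_filter <- function(contigs, min_length = 1500L) {
  w <- BiocGenerics::width(contigs)
  keep <- w >= min_length
  list(kept = contigs[keep],
       report = list(n_in = length(w), n_kept = sum(keep),
                     n_dropped = sum(!keep)))
}

#' Combine predictor outputs into one evidence table
#'
#' Missing entries (a tool not run, or a contig a tool did not report) are
#' non-reporting, never failures.
#'
#' @param contig_lengths named numeric vector (or data.frame with
#'   `contig_id`, `length`) of contig lengths in bp.
#' @param virsorter data.frame with `contig_id`, `category` and, for
#'   prophage categories, 1-based inclusive `start`, `end`; or `NULL`.
#' @param virfinder data.frame with `contig_id`, `score`, `pvalue`; or
#'   `NULL`.
#' @param pprmeta data.frame with `contig_id`, `class` (phage /
#'   chromosome / plasmid); or `NULL`.
#' @return data.table, one row per contig: `contig_id`, `length`,
#'   `virsorter_category`, `vf_score`, `vf_pvalue`, `pprmeta_class`,
#'   `regions` (list of data.tables with 0-based half-open `start`, `end`).
#' @export
combine_evidence <- function(contig_lengths, virsorter = NULL,
                             virfinder = NULL, pprmeta = NULL) {
  if (is.data.frame(contig_lengths)) {
    len <- as.data.table(contig_lengths)[, .(contig_id = as.character(contig_id),
                                             length = as.numeric(length))]
  } else {
    len <- data.table(contig_id = names(contig_lengths),
                      length = as.numeric(contig_lengths))
  }
  ev <- copy(len)
  ev[, `:=`(virsorter_category = NA_integer_, vf_score = NA_real_,
            vf_pvalue = NA_real_, pprmeta_class = NA_character_)]
  # list column of per-contig region tables (empty placeholder, not NULL,
  # so single-row assignment does not look like a column delete)
  ev$regions <- rep(list(data.table(start = numeric(0), end = numeric(0))),
                    nrow(ev))

  if (!is.null(virsorter) && nrow(virsorter)) {
    vs <- as.data.table(virsorter)
    vs[, contig_id := as.character(contig_id)]
    if (any(!vs$category %in% 1:6))
      stop("VirSorter category outside 1-6 for contig(s): ",
           paste(vs$contig_id[!vs$category %in% 1:6], collapse = ", "))
    for (cid in unique(vs$contig_id)) {
      rows <- vs[contig_id == cid]
      i <- match(cid, ev$contig_id)
      if (is.na(i)) next
      set(ev, i, "virsorter_category", as.integer(min(rows$category)))
      if (all(c("start", "end") %in% names(rows))) {
        rg <- rows[!is.na(start) & !is.na(end),
                   .(start = as.numeric(start) - 1, end = as.numeric(end))]
        if (nrow(rg)) ev$regions[[i]] <- rg
      }
    }
  }
  if (!is.null(virfinder) && nrow(virfinder)) {
    vf <- as.data.table(virfinder)
    vf[, contig_id := as.character(contig_id)]
    i <- match(vf$contig_id, ev$contig_id)
    ok <- !is.na(i)
    set(ev, i[ok], "vf_score", as.numeric(vf$score[ok]))
    set(ev, i[ok], "vf_pvalue", as.numeric(vf$pvalue[ok]))
  }
  if (!is.null(pprmeta) && nrow(pprmeta)) {
    pm <- as.data.table(pprmeta)
    pm[, contig_id := as.character(contig_id)]
    i <- match(pm$contig_id, ev$contig_id)
    ok <- !is.na(i)
    set(ev, i[ok], "pprmeta_class", tolower(as.character(pm$class[ok])))
  }
  ev[]
}

#' Triage contigs from combined predictor evidence
#'
#' Verdicts, in precedence order:
#' \itemize{
#'   \item HC — VirSorter category 1 or 2 (whole-contig viral).
#'   \item PP — VirSorter prophage category 4 or 5 (category 6 only when
#'     `allow_cat6 = TRUE`); the prophage regions are attached.
#'   \item LC — any of: VirFinder p < 0.05 and score >= 0.9; p < 0.05 and
#'     score >= 0.7 with VirSorter category 3; p < 0.05 and score >= 0.7
#'     with a PPR-Meta phage call. Score boundaries are inclusive, the
#'     p-value boundary exclusive.
#'   \item excluded — no rule fires.
#' }
#' The `rule` tag reports the first satisfied clause in the order above.
#'
#' @param evidence table from [combine_evidence()].
#' @param allow_cat6 treat VirSorter category 6 as PP-eligible
#'   (default `FALSE`).
#' @return data.table with `contig_id`, `verdict`, `rule`, `regions`
#'   (list column; non-empty only for PP).
#' @export
triage_contigs <- function(evidence, allow_cat6 = FALSE) {
  ev <- as.data.table(evidence)
  pp_cats <- if (allow_cat6) c(4L, 5L, 6L) else c(4L, 5L)
  n <- nrow(ev)
  verdict <- rep("excluded", n)
  rule <- rep("none", n)
  regions <- vector("list", n)
  for (i in seq_len(n)) {
    cat_i <- ev$virsorter_category[[i]]
    p <- ev$vf_pvalue[[i]]; s <- ev$vf_score[[i]]
    vf_sig <- !is.na(p) && !is.na(s) && p < 0.05
    if (!is.na(cat_i) && cat_i %in% c(1L, 2L)) {
      verdict[i] <- "HC"
      rule[i] <- sprintf("virsorter_category_%d", cat_i)
    } else if (!is.na(cat_i) && cat_i %in% pp_cats) {
      rg <- ev$regions[[i]]
      if (is.null(rg) || !nrow(rg)) {
        # prophage call without coordinates: take the whole contig
        rg <- data.table(start = 0, end = ev$length[[i]])
      }
      verdict[i] <- "PP"
      rule[i] <- sprintf("virsorter_prophage_category_%d", cat_i)
      regions[[i]] <- rg
    } else if (vf_sig && s >= 0.9) {
      verdict[i] <- "LC"; rule[i] <- "virfinder_score_0.9"
    } else if (vf_sig && s >= 0.7 && !is.na(cat_i) && cat_i == 3L) {
      verdict[i] <- "LC"; rule[i] <- "virfinder_0.7_virsorter_cat3"
    } else if (vf_sig && s >= 0.7 &&
               identical(ev$pprmeta_class[[i]], "phage")) {
      verdict[i] <- "LC"; rule[i] <- "virfinder_0.7_pprmeta_phage"
    }
  }
  data.table(contig_id = ev$contig_id, verdict = verdict, rule = rule,
             regions = regions)
}

#' Excise prophage regions from a contig
#'
#' @param sequence a single [Biostrings::DNAString], a one-element
#'   `DNAStringSet`, or a character string.
#' @param regions data.frame with 0-based half-open `start`, `end`.
#' @param contig_id id used for naming; defaults to the sequence name.
#' @return a `DNAStringSet` named `contigID|prophage-start:end`.
#' @export
extract_regions <- function(sequence, regions, contig_id = NULL) {
  if (is.character(sequence)) sequence <- Biostrings::DNAStringSet(sequence)
  if (methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAStringSet(sequence)
  if (is.null(contig_id))
    contig_id <- names(sequence)[[1L]] %||% "contig"
  rg <- as.data.table(regions)
  len <- BiocGenerics::width(sequence)[[1L]]
  if (any(rg$start < 0 | rg$end > len | rg$start >= rg$end))
    stop("region out of range for ", contig_id, " (length ", len, ")")
  subs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(rg)), function(i)
    Biostrings::subseq(sequence[[1L]], start = rg$start[[i]] + 1L,
                       end = rg$end[[i]])))
  names(subs) <- sprintf("%s|prophage-%d:%d", contig_id,
                         as.integer(rg$start), as.integer(rg$end))
  subs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read predictor output tables
#'
#' `read_virsorter_csv`: affiliation-style CSV with columns `contig_id`,
#' `category` and optional 1-based `start`, `end` for prophage rows.
#' `read_virfinder_tsv`: TSV with `name`, `length`, `score`, `pvalue`.
#' `read_pprmeta_csv`: CSV whose header carries a `Header` id column and a
#' class column (`Possible_source` or `class`).
#'
#' @param path file path.
#' @return a data.table in the column convention of [combine_evidence()].
#' @export
read_virsorter_csv <- function(path) {
  dt <- fread(path, header = TRUE)
  setnames(dt, names(dt), tolower(names(dt)))
  stopifnot(all(c("contig_id", "category") %in% names(dt)))
  dt[, contig_id := as.character(contig_id)]
  dt[]
}

#' @rdname read_virsorter_csv
#' @export
read_virfinder_tsv <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  setnames(dt, names(dt), tolower(names(dt)))
  if ("name" %in% names(dt)) setnames(dt, "name", "contig_id")
  stopifnot(all(c("contig_id", "score", "pvalue") %in% names(dt)))
  dt[, contig_id := as.character(contig_id)]
  dt[]
}

#' @rdname read_virsorter_csv
#' @export
read_pprmeta_csv <- function(path) {
  dt <- fread(path, header = TRUE)
  nm <- names(dt)
  id_col <- nm[tolower(nm) %in% c("header", "contig_id")][1L]
  cls_col <- nm[tolower(nm) %in% c("possible_source", "class")][1L]
  if (is.na(id_col) || is.na(cls_col))
    stop("PPR-Meta table needs a Header/contig_id and a class column")
  out <- data.table(contig_id = as.character(dt[[id_col]]),
                    class = tolower(as.character(dt[[cls_col]])))
  out[]
}

#' Run the full triage step on files
#'
#' Reads the contig FASTA and whichever predictor tables are provided,
#' length-filters, triages, and writes the HC/LC FASTA, the PP FASTA of
#' excised regions, an assignments TSV and a BED of prophage regions.
#'
#' @param fasta contig FASTA path.
#' @param virsorter,virfinder,pprmeta predictor table paths (each optional).
#' @param min_length length filter in bp (default 1500).
#' @param allow_cat6 see [triage_contigs()].
#' @param checkv optional CheckV summary TSV (`contig_id` + any columns)
#'   merged verbatim into the assignments report.
#' @param out_dir output directory (created if needed).
#' @return the assignments data.table, invisibly writing the outputs.
#' @export
run_triage <- function(fasta, virsorter = NULL, virfinder = NULL,
                       pprmeta = NULL, min_length = 1500L,
                       allow_cat6 = FALSE, checkv = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  lf <- length_filter(contigs, min_length)
  kept <- lf$kept
  ev <- combine_evidence(
    stats::setNames(BiocGenerics::width(kept), names(kept)),
    virsorter = if (!is.null(virsorter)) read_virsorter_csv(virsorter),
    virfinder = if (!is.null(virfinder)) read_virfinder_tsv(virfinder),
    pprmeta = if (!is.null(pprmeta)) read_pprmeta_csv(pprmeta)
  )
  asg <- triage_contigs(ev, allow_cat6 = allow_cat6)

  hc_lc <- asg[verdict %in% c("HC", "LC")]
  if (nrow(hc_lc))
    Biostrings::writeXStringSet(kept[hc_lc$contig_id],
                                file.path(out_dir, "hc_lc_contigs.fasta"))
  pp <- asg[verdict == "PP"]
  if (nrow(pp)) {
    pieces <- do.call(c, lapply(seq_len(nrow(pp)), function(i)
      extract_regions(kept[pp$contig_id[[i]]], pp$regions[[i]],
                      contig_id = pp$contig_id[[i]])))
    Biostrings::writeXStringSet(pieces,
                                file.path(out_dir, "prophage_regions.fasta"))
    bed <- rbindlist(lapply(seq_len(nrow(pp)), function(i)
      data.table(chrom = pp$contig_id[[i]],
                 start = as.integer(pp$regions[[i]]$start),
                 end = as.integer(pp$regions[[i]]$end))))
    fwrite(bed, file.path(out_dir, "prophage_regions.bed"),
           sep = "\t", col.names = FALSE)
  }
  report <- asg[, .(contig_id, verdict, rule)]
  if (!is.null(checkv)) {
    cv <- fread(checkv, sep = "\t", header = TRUE)
    setnames(cv, 1L, "contig_id")
    cv[, contig_id := as.character(contig_id)]
    report <- merge(report, cv, by = "contig_id", all.x = TRUE)
  }
  fwrite(report, file.path(out_dir, "triage_assignments.tsv"), sep = "\t")
  asg
}
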