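#' @import data.table
NULL

#' Working taxonomic ranks used throughout the package
#'
#' Marker calibration, CDS statistics and the voting classifier all operate
#' on the same four ranks, tried from finest to coarsest.
#'
#' @export
WORK_RANKS <- c("genus", "subfamily", "family", "order")

# Rank vocabulary accepted on input; anything else is demoted to "no-rank"
# with a warning so NCBI-style trees (clades, species groups, ...) load.
KNOWN_RANKS <- c(
  WORK_RANKS, "species", "class", "no-rank",
  "superkingdom", "kingdom", "realm", "subrealm", "phylum", "subphylum",
  "subclass", "suborder", "subgenus", "clade", "strain", "serotype",
  "isolate", "genotype", "species group", "species subgroup", "biotype",
  "forma", "varietas"
)

#' Construct a validated taxonomy tree
#'
#' A rank-labelled parent-pointer tree over opaque taxon ids. Exactly one
#' root is required (a node whose parent is itself, empty or `NA`); every
#' other parent must exist in the table and no cycles are allowed. Taxon
#' identity is by id; names are display-only.
#'
#' @param taxid character or integer vector of node ids (unique).
#' @param name display names, same length as `taxid`.
#' @param rank rank strings; unknown ranks are kept as `"no-rank"` with a
#'   warning.
#' @param parent parent ids; the root points at itself or at `NA`/`""`.
#' @return an object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(taxid, name, rank, parent) {
  taxid <- as.character(taxid)
  parent <- as.character(parent)
  name <- as.character(name)
  rank <- tolower(trimws(as.character(rank)))
  rank[rank == "no rank"] <- "no-rank"
  stopifnot(length(taxid) > 0L,
            length(name) == length(taxid),
            length(rank) == length(taxid),
            length(parent) == length(taxid))
  if (anyDuplicated(taxid))
    stop("duplicate taxon id(s): ",
         paste(unique(taxid[duplicated(taxid)]), collapse = ", "))
  unknown <- setdiff(unique(rank), KNOWN_RANKS)
  if (length(unknown)) {
    warning("unknown rank string(s) kept as 'no-rank': ",
            paste(unknown, collapse = ", "))
    rank[rank %in% unknown] <- "no-rank"
  }
  is_root <- is.na(parent) | parent == "" | parent == taxid
  if (sum(is_root) > 1L)
    stop("structural error: multiple roots / self-parent cycles at id(s): ",
         paste(taxid[is_root], collapse = ", "))
  if (sum(is_root) == 0L)
    stop("structural error: no root node (parent == self, empty or NA)")
  root <- taxid[is_root]
  missing_par <- setdiff(parent[!is_root], taxid)
  if (length(missing_par))
    stop("parent id(s) absent from the node table: ",
         paste(missing_par, collapse = ", "))

  names(name) <- taxid
  names(rank) <- taxid
  names(parent) <- taxid
  parent[is_root] <- root

  # reachability from the root doubles as cycle detection
  kids <- split(taxid[!is_root], parent[!is_root])
  seen <- structure(logical(length(taxid)), names = taxid)
  frontier <- root
  while (length(frontier)) {
    seen[frontier] <- TRUE
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  if (!all(seen))
    stop("cycle detected involving taxon id(s): ",
         paste(names(seen)[!seen], collapse = ", "))

  structure(
    list(taxid = taxid, name = name, rank = rank, parent = parent,
         root = root, children = kids),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d taxa, root %s (%s)\n",
              length(x$taxid), x$root, x$name[x$root]))
  tab <- table(factor(x$rank, levels = unique(c(WORK_RANKS, "species",
                                                "class", "no-rank"))))
  tab <- tab[tab > 0]
  cat("  ranks:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.taxonomy_tree <- function(x, ...) {
  data.frame(taxid = x$taxid, name = unname(x$name[x$taxid]),
             rank = unname(x$rank[x$taxid]),
             parent_taxid = unname(x$parent[x$taxid]),
             stringsAsFactors = FALSE)
}

#' Number of taxa in a taxonomy tree
#' @param tree a `taxonomy_tree`.
#' @export
n_taxa <- function(tree) length(tree$taxid)

.check_taxid <- function(tree, taxid) {
  bad <- setdiff(as.character(taxid), tree$taxid)
  if (length(bad))
    stop("unknown taxon id(s): ", paste(bad, collapse = ", "))
}

#' Ancestor chain of a taxon
#'
#' @param tree a `taxonomy_tree`.
#' @param taxid a single taxon id present in the tree.
#' @return character vector from `taxid` up to (and including) the root.
#' @export
ancestor_chain <- function(tree, taxid) {
  taxid <- as.character(taxid)
  .check_taxid(tree, taxid)
  chain <- taxid
  while (taxid != tree$root) {
    taxid <- tree$parent[[taxid]]
    chain <- c(chain, taxid)
  }
  chain
}

#' Lineage of a taxon at the four working ranks
#'
#' Returns, for each of genus/subfamily/family/order, the unique ancestor
#' (or the taxon itself) holding that rank, or `NA` if the lineage has no
#' node at that rank. Nodes at other ranks are skipped transparently.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxid a single taxon id present in the tree.
#' @return a list with entries `genus`, `subfamily`, `family`, `order`
#'   (taxon ids or `NA`) and `chain` (the full ancestor chain).
#' @export
lineage_of <- function(tree, taxid) {
  chain <- ancestor_chain(tree, taxid)
  ranks <- tree$rank[chain]
  slots <- lapply(WORK_RANKS, function(r) {
    hit <- chain[ranks == r]
    if (length(hit)) hit[[1L]] else NA_character_
  })
  names(slots) <- WORK_RANKS
  c(slots, list(chain = chain))
}

#' Lineage table for many taxa at once
#'
#' Vectorised companion of [lineage_of()]: one row per input id, columns
#' `taxid`, `genus`, `subfamily`, `family`, `order`.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxids taxon ids; defaults to every node in the tree.
#' @return a `data.table`.
#' @export
lineage_table <- function(tree, taxids = tree$taxid) {
  taxids <- as.character(taxids)
  .check_taxid(tree, taxids)
  rows <- lapply(taxids, function(id) {
    l <- lineage_of(tree, id)
    data.table(taxid = id, genus = l$genus, subfamily = l$subfamily,
               family = l$family, order = l$order)
  })
  rbindlist(rows)
}

#' Descendants of a taxon
#'
#' All nodes whose ancestor chain contains `taxon`, excluding `taxon`
#' itself.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxon a single taxon id present in the tree.
#' @return character vector of taxon ids (possibly empty).
#' @export
descendants <- function(tree, taxon) {
  taxon <- as.character(taxon)
  .check_taxid(tree, taxon)
  out <- character(0)
  frontier <- unlist(tree$children[taxon], use.names = FALSE)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(tree$children[frontier], use.names = FALSE)
  }
  out
}

#' Load a taxonomy from disk
#'
#' Two dialects are supported: a simplified 4-column lineage TSV
#' (`taxid`, `name`, `rank`, `parent_taxid`; header required) and the NCBI
#' `nodes.dmp`/`names.dmp` pair (fields separated by `"\t|\t"`). Both
#' produce identical trees for equivalent content.
#'
#' @param source path to the lineage TSV or to `nodes.dmp`.
#' @param dialect `"lineage-tsv"` or `"ncbi-dmp"`.
#' @param names_file path to `names.dmp` (dmp dialect only; optional —
#'   without it node names default to their ids).
#' @return a `taxonomy_tree`.
#' @export
load_taxonomy <- function(source, dialect = c("lineage-tsv", "ncbi-dmp"),
                          names_file = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("taxonomy file not found: ", source)
  if (dialect == "lineage-tsv") {
    dt <- fread(source, sep = "\t", colClasses = "character", header = TRUE)
    need <- c("taxid", "name", "rank", "parent_taxid")
    if (!all(need %in% names(dt)))
      stop("lineage TSV must carry columns: ", paste(need, collapse = ", "))
    taxonomy_tree(dt$taxid, dt$name, dt$rank, dt$parent_taxid)
  } else {
    nodes <- .read_dmp(source)
    if (ncol(nodes) < 3L) stop("nodes.dmp needs >= 3 fields per row")
    taxid <- nodes[[1L]]
    parent <- nodes[[2L]]
    rank <- nodes[[3L]]
    nm <- taxid
    if (!is.null(names_file)) {
      nd <- .read_dmp(names_file)
      # keep scientific names when the name-class column is present
      if (ncol(nd) >= 4L) nd <- nd[nd[[4L]] == "scientific name", ]
      nm_map <- structure(nd[[2L]], names = nd[[1L]])
      found <- taxid %in% names(nm_map)
      nm[found] <- nm_map[taxid[found]]
    }
    taxonomy_tree(taxid, nm, rank, parent)
  }
}

# "\t|\t"-separated NCBI dump rows, trailing "\t|" stripped
.read_dmp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t")
  nfield <- max(lengths(parts))
  cols <- lapply(seq_len(nfield), function(i)
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else "",
           character(1)))
  as.data.table(cols)
}

#' Write a normalized lineage TSV
#'
#' @param tree a `taxonomy_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lineage_tsv <- function(tree, path) {
  df <- as.data.frame(tree)
  df$parent_taxid[df$taxid == tree$root] <- tree$root
  fwrite(df, path, sep = "\t")
  invisible(path)
}
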