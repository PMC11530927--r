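# Taxonomy handling: NCBI-taxdump-dialect loading, projection of TaxIDs onto
# the fixed seven-rank ladder, and the three per-peptide consensus (LCA)
# algorithms: conventional (CON), frequency-weighted (W), bitscore (BIT).

#' Construct a taxonomy tree
#'
#' @param parent Named integer vector mapping taxid -> parent taxid (names
#'   are taxids as strings). The root is its own parent.
#' @param rank Named character vector mapping taxid -> rank name.
#' @param name Named character vector mapping taxid -> scientific name.
#' @return A validated `tax_tree`.
#' @export
tax_tree <- function(parent, rank, name) {
  ids <- names(parent)
  stopifnot(!is.null(ids), setequal(ids, names(rank)),
            setequal(ids, names(name)))
  tree <- structure(list(parent = parent, rank = rank[ids], name = name[ids]),
                    class = "tax_tree")
  validate_tax_tree(tree)
  tree
}

validate_tax_tree <- function(tree) {
  ids <- names(tree$parent)
  roots <- ids[tree$parent == as.integer(ids)]
  if (length(roots) != 1) {
    stop("taxonomy must have exactly one self-parented root, found ",
         length(roots))
  }
  if (any(!as.character(tree$parent) %in% ids)) {
    stop("parent taxids missing from the node set")
  }
  # cycle check: chase parents; path length may never exceed the node count
  n <- length(ids)
  for (id in ids) {
    steps <- 0L
    cur <- id
    while (tree$parent[[cur]] != as.integer(cur)) {
      cur <- as.character(tree$parent[[cur]])
      steps <- steps + 1L
      if (steps > n) stop("cycle detected in taxonomy at taxid ", id)
    }
  }
  invisible(tree)
}

#' @export
print.tax_tree <- function(x, ...) {
  cat("Taxonomy tree:", length(x$parent), "taxa;",
      sum(x$rank == "species"), "species\n")
  invisible(x)
}

parse_dmp <- function(path) {
  lines <- readLines(path)
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t\\|\t")
}

#' Load a taxonomy from NCBI taxdump files or a lineage table
#'
#' Reads `nodes.dmp`/`names.dmp` in the `|`-delimited dump dialect from a
#' directory, or a prebuilt 8-column lineage TSV (header `taxid` plus the
#' seven ladder ranks as name columns) from which a tree is reconstructed
#' with synthetic internal taxids. Tree invariants (single self-parented
#' root, no cycles) are verified on load.
#'
#' @param path Directory containing `nodes.dmp` and `names.dmp`, or the path
#'   of a lineage TSV.
#' @return A `tax_tree`.
#' @export
load_taxdump <- function(path) {
  if (dir.exists(path)) {
    nodes_f <- file.path(path, "nodes.dmp")
    names_f <- file.path(path, "names.dmp")
    if (!file.exists(nodes_f)) stop("missing nodes.dmp in ", path)
    if (!file.exists(names_f)) stop("missing names.dmp in ", path)
    nodes <- parse_dmp(nodes_f)
    ids <- vapply(nodes, `[[`, character(1), 1)
    parent <- setNames(as.integer(vapply(nodes, `[[`, character(1), 2)), ids)
    rank <- setNames(vapply(nodes, function(x)
      if (length(x) >= 3) x[[3]] else "no rank", character(1)), ids)
    nm <- parse_dmp(names_f)
    cls <- vapply(nm, function(x) if (length(x) >= 4) x[[4]] else "",
                  character(1))
    sci <- nm[cls == "scientific name" | cls == ""]
    name <- setNames(vapply(sci, `[[`, character(1), 2),
                     vapply(sci, `[[`, character(1), 1))
    name <- name[!duplicated(names(name))]
    missing_names <- setdiff(ids, names(name))
    name[missing_names] <- paste0("taxid:", missing_names)
    return(tax_tree(parent, rank, name[ids]))
  }
  lineage_table_to_tree(readr::read_tsv(path, show_col_types = FALSE,
                                        progress = FALSE))
}

# Rebuild a tree from an 8-column lineage table (taxid + 7 rank names).
lineage_table_to_tree <- function(df) {
  stopifnot("taxid" %in% names(df), all(TAX_RANKS %in% names(df)))
  parent <- c("1" = 1L)
  rank <- c("1" = "no rank")
  name <- c("1" = "root")
  next_id <- -1L  # synthetic internal taxids are negative, never collide
  key_id <- c(root = 1L)
  for (i in seq_len(nrow(df))) {
    anc <- 1L
    key <- "root"
    for (r in TAX_RANKS) {
      val <- df[[r]][i]
      if (is.na(val) || !nzchar(val)) break
      key <- paste(key, val, sep = "\r")
      if (is.null(key_id[key]) || is.na(key_id[key])) {
        id <- if (r == "species") as.integer(df$taxid[i]) else next_id
        if (r != "species") next_id <- next_id - 1L
        key_id[key] <- id
        ids <- as.character(id)
        parent[ids] <- anc
        rank[ids] <- r
        name[ids] <- val
      }
      anc <- key_id[[key]]
    }
  }
  tax_tree(parent, rank, name)
}

#' Write a taxonomy tree as taxdump-dialect files
#'
#' @param tree A `tax_tree`.
#' @param dir Output directory (created if needed); writes `nodes.dmp` and
#'   `names.dmp`.
#' @return `dir`, invisibly.
#' @export
write_taxdump <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(tree$parent)
  writeLines(paste0(ids, "\t|\t", tree$parent, "\t|\t", tree$rank, "\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(paste0(ids, "\t|\t", tree$name, "\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  invisible(dir)
}

#' Project TaxIDs onto the seven-rank lineage ladder
#'
#' Chases parents to the root and records the taxid and scientific name at
#' each of the canonical ranks (superkingdom, phylum, class, order, family,
#' genus, species); taxa at intermediate ranks are skipped. TaxIDs absent
#' from the tree yield all-`NA` rows.
#'
#' @param tree A `tax_tree`.
#' @param taxids Integer vector of TaxIDs.
#' @return Tibble with column `taxid`, one `<rank>_taxid` integer column and
#'   one `<rank>` name column per ladder rank.
#' @export
tax_lineage <- function(tree, taxids) {
  uniq <- unique(taxids)
  known <- as.character(uniq) %in% names(tree$parent)
  rows <- lapply(seq_along(uniq), function(i) {
    out_id <- setNames(rep(NA_integer_, 7), paste0(TAX_RANKS, "_taxid"))
    out_nm <- setNames(rep(NA_character_, 7), TAX_RANKS)
    if (known[i]) {
      cur <- as.character(uniq[i])
      repeat {
        r <- tree$rank[[cur]]
        if (r %in% TAX_RANKS) {
          out_id[paste0(r, "_taxid")] <- as.integer(cur)
          out_nm[r] <- tree$name[[cur]]
        }
        nxt <- as.character(tree$parent[[cur]])
        if (nxt == cur) break
        cur <- nxt
      }
    }
    tibble::as_tibble(c(list(taxid = uniq[i]), as.list(out_id),
                        as.list(out_nm)))
  })
  lin <- dplyr::bind_rows(rows)
  lin[match(taxids, lin$taxid), ]
}

#' LCA parameter set
#'
#' @param method Consensus algorithm: `"CON"` (conventional), `"W"`
#'   (frequency-weighted) or `"BIT"` (bitscore).
#' @param weight_cutoff Cumulative-weight (W) or bitscore-share (BIT) cutoff
#'   in (0, 1]; default 0.6.
#' @param min_bitscore Minimum bitscore the hits are expected to satisfy
#'   (default 25); recorded for provenance, filtering happens upstream in
#'   [filter_hits()].
#' @return An `lca_params` list.
#' @export
lca_params <- function(method = c("W", "CON", "BIT"), weight_cutoff = 0.6,
                       min_bitscore = 25) {
  method <- match.arg(method)
  stopifnot(weight_cutoff > 0, weight_cutoff <= 1)
  structure(list(method = method, weight_cutoff = weight_cutoff,
                 min_bitscore = min_bitscore), class = "lca_params")
}

empty_lineage_row <- function() {
  out <- c(as.list(setNames(rep(NA_integer_, 7), paste0(TAX_RANKS,
                                                        "_taxid"))),
           as.list(setNames(rep(NA_character_, 7), TAX_RANKS)))
  tibble::as_tibble(out)
}

#' Conventional LCA of a set of lineages
#'
#' Deepest rank at which all lineages agree (non-missing and identical);
#' deeper ranks are left empty. Disagreement at superkingdom yields the
#' all-empty lineage (root).
#'
#' @param lineages Tibble of lineage rows as produced by [tax_lineage()].
#' @return One-row lineage tibble.
#' @export
lca_conventional <- function(lineages) {
  out <- empty_lineage_row()
  if (nrow(lineages) == 0) return(out)
  for (r in TAX_RANKS) {
    ids <- lineages[[paste0(r, "_taxid")]]
    if (anyNA(ids) || length(unique(ids)) != 1) break
    out[[paste0(r, "_taxid")]] <- ids[1]
    out[[r]] <- lineages[[r]][1]
  }
  out
}

#' Frequency-weighted LCA for one peptide
#'
#' The taxa hit by the peptide are sorted by descending global weight (the
#' frequency of each taxid over all target hits of the run), the weights are
#' cumulatively summed and normalized to 1 over the peptide's taxa, and the
#' minimal prefix reaching `weight_cutoff` (inclusive of the crossing taxon)
#' is retained; the result is the conventional LCA of the retained lineages.
#' Ties in weight are broken by ascending taxid. Taxa without global
#' evidence (possible for decoy-only taxa) get an infinitesimal weight so
#' they are retained only in the cutoff -> 1 limit, which keeps the
#' `cutoff = 1` result identical to the conventional LCA; when no taxon has
#' global evidence the weights fall back to uniform.
#'
#' @param hit_lineages Lineage rows of the peptide's hit taxa (one per
#'   distinct taxid, column `taxid` present).
#' @param global_weights Named numeric vector: taxid -> frequency over all
#'   target hits.
#' @param weight_cutoff Cumulative cutoff in (0, 1].
#' @return One-row lineage tibble.
#' @export
lca_weighted <- function(hit_lineages, global_weights, weight_cutoff = 0.6) {
  if (nrow(hit_lineages) == 0) return(empty_lineage_row())
  taxa <- unique(hit_lineages$taxid)
  w <- global_weights[as.character(taxa)]
  w[is.na(w)] <- 0
  if (all(w <= 0)) {
    w[] <- 1  # decoy-only taxa: no global evidence, fall back to uniform
  } else {
    # zero-weight taxa get an infinitesimal weight: they never help reach
    # the cutoff but are retained in the cutoff -> 1 limit (W(1) = CON)
    w[w <= 0] <- sum(w) * 1e-9 / length(w)
  }
  ord <- order(-w, taxa)
  cum <- cumsum(w[ord]) / sum(w)
  keep <- taxa[ord][seq_len(which(cum >= weight_cutoff - 1e-12)[1])]
  lca_conventional(hit_lineages[hit_lineages$taxid %in% keep, , drop = FALSE])
}

#' Bitscore LCA for one peptide
#'
#' Walks the rank ladder top-down; at each rank the bitscores of the
#' peptide's hits are summed per taxon (restricted to hits compatible with
#' the taxa already assigned at shallower ranks and carrying a taxon at the
#' current rank). A taxon whose share of that total exceeds `weight_cutoff`
#' is assigned; if none does, the rank and all deeper ranks stay empty. For
#' any cutoff > 0.5 at most one taxon can qualify per rank.
#'
#' @param hits Tibble with one row per hit: `bitscore` plus lineage columns
#'   as from [tax_lineage()].
#' @param weight_cutoff Share cutoff in (0, 1].
#' @return One-row lineage tibble.
#' @export
lca_bitscore <- function(hits, weight_cutoff = 0.6) {
  out <- empty_lineage_row()
  if (nrow(hits) == 0) return(out)
  compatible <- rep(TRUE, nrow(hits))
  for (r in TAX_RANKS) {
    idc <- paste0(r, "_taxid")
    eligible <- compatible & !is.na(hits[[idc]])
    if (!any(eligible)) break
    sums <- tapply(hits$bitscore[eligible], hits[[idc]][eligible], sum)
    shares <- sums / sum(sums)
    top <- which.max(shares)
    if (shares[top] <= weight_cutoff) break
    winner <- as.integer(names(shares)[top])
    out[[idc]] <- winner
    out[[r]] <- hits[[r]][eligible & hits[[idc]] == winner][1]
    compatible <- compatible & !is.na(hits[[idc]]) & hits[[idc]] == winner
  }
  out
}

#' Per-query consensus taxonomy over an alignment run
#'
#' Expands hits to one row per subject taxid, maps taxids to ladder lineages
#' (hits with taxids absent from the tree are dropped with a message), and
#' computes the consensus lineage per query with the selected LCA method.
#' Decoy queries are processed identically and flagged, but never contribute
#' to the global weights of the W method.
#'
#' @param hits Bitscore-filtered hits tibble (see [filter_hits()]).
#' @param tree A `tax_tree`.
#' @param params An [lca_params()].
#' @return Tibble with one row per query: `query_id`, `is_decoy_query`,
#'   `method`, `n_hits`, plus the 14 lineage columns.
#' @export
assign_lca <- function(hits, tree, params = lca_params()) {
  if (nrow(hits) == 0) {
    return(dplyr::bind_cols(
      tibble::tibble(query_id = character(), is_decoy_query = logical(),
                     method = character(), n_hits = integer()),
      empty_lineage_row()[0, ]))
  }
  long <- tidyr::unnest(hits[c("query_id", "is_decoy_query", "bitscore",
                               "subject_taxids")],
                        "subject_taxids") |>
    dplyr::rename(taxid = "subject_taxids")
  known <- as.character(long$taxid) %in% names(tree$parent)
  if (any(!known)) {
    message("assign_lca: dropped ", sum(!known),
            " hit(s) with taxids absent from the taxonomy")
    long <- long[known, , drop = FALSE]
  }
  if (nrow(long) == 0) return(assign_lca(hits[0, ], tree, params))
  lin <- tax_lineage(tree, long$taxid)
  long <- dplyr::bind_cols(long, lin[-1])

  global_weights <- if (params$method == "W") {
    tab <- table(long$taxid[!long$is_decoy_query])
    setNames(as.numeric(tab), names(tab))
  }

  one_query <- function(d) {
    res <- switch(params$method,
      CON = lca_conventional(dplyr::distinct(d, .data$taxid,
                                             .keep_all = TRUE)),
      W = lca_weighted(dplyr::distinct(d, .data$taxid, .keep_all = TRUE),
                       global_weights, params$weight_cutoff),
      BIT = lca_bitscore(d, params$weight_cutoff))
    dplyr::bind_cols(
      tibble::tibble(is_decoy_query = d$is_decoy_query[1],
                     method = params$method,
                     n_hits = length(unique(d$taxid))),
      res)
  }
  long |>
    dplyr::group_by(.data$query_id) |>
    dplyr::group_modify(function(d, key) one_query(d)) |>
    dplyr::ungroup()
}
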