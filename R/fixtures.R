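# Synthetic data generators: taxonomies, proteomes, tryptic peptides and
# error-perturbed de novo experiments with ground truth, so every pipeline
# stage is testable without downloads.

syllables <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu", "ne",
               "pa", "qui", "ro", "su", "ta", "ve", "xi", "zo")

random_name <- function(n_syl = 3) {
  s <- paste(sample(syllables, n_syl, replace = TRUE), collapse = "")
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

#' Generate a synthetic seven-rank taxonomy
#'
#' Builds a full ladder (one superkingdom; phyla/classes/orders nested above
#' the families; one genus per species) with `n_families * species_per_family`
#' species. The shape is deterministic; taxon names are drawn from a seeded
#' name generator, so different seeds give different names over an identical
#' topology.
#'
#' @param n_families Number of families (>= 1).
#' @param species_per_family Species (each in its own genus) per family.
#' @param seed Integer seed for the names.
#' @return A `tax_tree`; the species taxids are available as
#'   `attr(tree, "species")`.
#' @export
synth_taxonomy <- function(n_families, species_per_family, seed = NULL) {
  stopifnot(n_families >= 1, species_per_family >= 1)
  with_seed_if(seed, {
    parent <- c("1" = 1L)
    rank <- c("1" = "no rank")
    name <- c("1" = "root")
    nid <- 1L
    add <- function(p, r, suffix = "") {
      nid <<- nid + 1L
      id <- as.character(nid)
      parent[id] <<- as.integer(p)
      rank[id] <<- r
      name[id] <<- paste0(random_name(), suffix)
      nid
    }
    sk <- add(1L, "superkingdom")
    n_orders <- max(1L, ceiling(n_families / 2))
    n_classes <- max(1L, ceiling(n_orders / 2))
    n_phyla <- max(1L, ceiling(n_classes / 2))
    phyla <- vapply(seq_len(n_phyla), function(i) add(sk, "phylum"),
                    integer(1))
    classes <- vapply(seq_len(n_classes), function(i)
      add(phyla[(i - 1) %% n_phyla + 1], "class"), integer(1))
    orders <- vapply(seq_len(n_orders), function(i)
      add(classes[(i - 1) %% n_classes + 1], "order", "ales"), integer(1))
    families <- vapply(seq_len(n_families), function(i)
      add(orders[(i - 1) %% n_orders + 1], "family", "aceae"), integer(1))
    species <- integer(0)
    for (f in families) {
      for (s in seq_len(species_per_family)) {
        g <- add(f, "genus")
        nid <- nid + 1L
        sp <- nid
        id <- as.character(sp)
        parent[id] <- g
        rank[id] <- "species"
        name[id] <- paste(name[[as.character(g)]], random_name(2))
        species <- c(species, sp)
      }
    }
    tree <- tax_tree(parent, rank, name)
    attr(tree, "species") <- species
    tree
  })
}

#' Generate synthetic proteomes for every species of a taxonomy
#'
#' Random protein sequences over the 19-letter (I-free) alphabet at uniform
#' residue frequencies; K/R occur at the alphabet rate, so tryptic digestion
#' yields realistic peptide lengths. Headers carry UniProtKB-style
#' `OX=<taxid>` tokens.
#'
#' @param tree A `tax_tree` (typically from [synth_taxonomy()]).
#' @param n_proteins Proteins per species (default 10).
#' @param len_range Protein length range, drawn uniformly (default 120-400).
#' @param seed Integer seed.
#' @return A `ref_db` tibble (`accession`, `taxid`, `seq`) with a `desc`
#'   column holding the `OX=` token for FASTA export.
#' @export
synth_proteomes <- function(tree, n_proteins = 10, len_range = c(120, 400),
                            seed = NULL) {
  species <- attr(tree, "species") %||%
    as.integer(names(tree$rank)[tree$rank == "species"])
  with_seed_if(seed, {
    rows <- lapply(species, function(sp) {
      lens <- sample(len_range[1]:len_range[2], n_proteins, replace = TRUE)
      tibble::tibble(
        accession = sprintf("SYN%05d_%03d", sp, seq_len(n_proteins)),
        taxid = as.integer(sp),
        seq = vapply(lens, function(L)
          paste(sample(ALPHABET19, L, replace = TRUE), collapse = ""),
          character(1))
      )
    })
    db <- dplyr::bind_rows(rows)
    db$desc <- paste0("synthetic protein OX=", db$taxid)
    structure(db, class = c("ref_db", class(db)))
  })
}

#' Tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P; peptides
#' spanning up to `missed_cleavages` skipped sites are added.
#'
#' @param protein Single protein sequence.
#' @param missed_cleavages Number of missed cleavages allowed (0-2 typical).
#' @param min_length,max_length Optional peptide length filter.
#' @return Character vector of peptides.
#' @export
#' @examples
#' tryptic_digest("AAKPMMKCCR")
tryptic_digest <- function(protein, missed_cleavages = 0, min_length = NULL,
                           max_length = NULL) {
  stopifnot(length(protein) == 1, nzchar(protein))
  cuts <- gregexpr("(?<=[KR])(?!P)", protein, perl = TRUE)[[1]]
  cuts <- cuts[cuts > 0]
  bounds <- c(1L, cuts, nchar(protein) + 1L)
  bounds <- unique(bounds[bounds <= nchar(protein) + 1L])
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1] - 1L
  peps <- character(0)
  for (mc in 0:missed_cleavages) {
    if (length(starts) <= mc) break
    i <- seq_len(length(starts) - mc)
    peps <- c(peps, substring(protein, starts[i], ends[i + mc]))
  }
  if (!is.null(min_length)) peps <- peps[nchar(peps) >= min_length]
  if (!is.null(max_length)) peps <- peps[nchar(peps) <= max_length]
  peps
}

#' Digest every protein of a reference database
#'
#' @param db A `ref_db` tibble.
#' @inheritParams tryptic_digest
#' @return Tibble with `accession`, `taxid`, `peptide`.
#' @export
digest_db <- function(db, missed_cleavages = 0, min_length = 7,
                      max_length = 30) {
  tibble::tibble(
    accession = db$accession, taxid = db$taxid,
    peptide = lapply(db$seq, tryptic_digest, missed_cleavages,
                     min_length, max_length)
  ) |>
    tidyr::unnest("peptide")
}

#' Assemble a synthetic microbial community
#'
#' Taxonomy, per-species proteomes, and a species abundance profile (expected
#' peptide fractions) drawn from a symmetric Dirichlet.
#'
#' @inheritParams synth_taxonomy
#' @param n_proteins Proteins per species.
#' @param dirichlet_alpha Concentration of the abundance profile (default 1;
#'   larger values give more even communities).
#' @param seed Integer seed driving taxonomy, proteomes and abundances.
#' @return A `synth_community` list: `tree`, `proteins` (a `ref_db`),
#'   `abundance` (tibble `taxid`, `species`, `family`, `fraction`).
#' @export
synth_community <- function(n_families = 10, species_per_family = 3,
                            n_proteins = 10, dirichlet_alpha = 1,
                            seed = NULL) {
  tree <- synth_taxonomy(n_families, species_per_family,
                         seed = child_seed(seed, 1))
  proteins <- synth_proteomes(tree, n_proteins, seed = child_seed(seed, 2))
  species <- attr(tree, "species")
  frac <- with_seed_if(child_seed(seed, 3), {
    g <- rgamma(length(species), shape = dirichlet_alpha)
    g / sum(g)
  })
  lin <- tax_lineage(tree, species)
  structure(
    list(tree = tree, proteins = proteins,
         abundance = tibble::tibble(taxid = species, species = lin$species,
                                    family = lin$family, fraction = frac)),
    class = "synth_community"
  )
}

#' @export
print.synth_community <- function(x, ...) {
  cat("Synthetic community:", nrow(x$abundance), "species,",
      length(unique(x$abundance$family)), "families,",
      nrow(x$proteins), "proteins\n")
  invisible(x)
}

#' Simulate a de novo sequencing experiment over a community
#'
#' Samples tryptic peptides according to the community abundance profile,
#' perturbs them with the combined sequencing-error model, and writes a
#' PEAKS-dialect de novo table. Scores are drawn so that error-bearing
#' peptides tend to lower ALC values (clean: normal(88, 5); altered:
#' normal(78, 8); clamped to \[40, 99\]). Ground truth (source species and
#' applied error) is returned alongside, keyed by scan.
#'
#' @param community A [synth_community()].
#' @param n_peptides Number of de novo rows to simulate.
#' @param error_cfg An [error_sim_config()]; its seed is overridden by
#'   `seed`.
#' @param seed Integer seed.
#' @param csv Optional path: write the PEAKS-dialect CSV there.
#' @return List with `denovo` (the PEAKS-dialect tibble), `truth` (tibble
#'   `query_id`, `scan`, `taxid`, `species`, `family`, `original`, `altered`,
#'   `error_type`, `changed`), and `csv` (path or `NULL`).
#' @export
synth_denovo_experiment <- function(community, n_peptides = 2000,
                                    error_cfg = error_sim_config(),
                                    seed = NULL, csv = NULL) {
  peps <- digest_db(community$proteins)
  pool <- split(peps$peptide, peps$taxid)
  ab <- community$abundance
  ab <- ab[as.character(ab$taxid) %in% names(pool), ]
  sampled <- with_seed_if(child_seed(seed, 11), {
    sp <- sample(ab$taxid, n_peptides, replace = TRUE, prob = ab$fraction)
    pep <- vapply(as.character(sp), function(t) {
      p <- pool[[t]]
      p[[sample.int(length(p), 1)]]
    }, character(1), USE.NAMES = FALSE)
    list(sp = sp, pep = pep)
  })
  error_cfg$seed <- child_seed(seed, 12)
  errored <- make_combined_dataset(sampled$pep, error_cfg)
  denovo <- with_seed_if(child_seed(seed, 13), {
    alc <- ifelse(errored$changed, rnorm(n_peptides, 78, 8),
                  rnorm(n_peptides, 88, 5))
    tibble::tibble(
      Peptide = errored$altered,
      `ALC (%)` = round(pmin(99, pmax(40, alc))),
      ppm = round(rnorm(n_peptides, 0, 5), 1),
      Area = round(rlnorm(n_peptides, 14, 1)),
      Scan = sprintf("F1:%d", seq_len(n_peptides))
    )
  })
  lin <- tax_lineage(community$tree, sampled$sp)
  truth <- tibble::tibble(
    query_id = paste0("scanF1_", seq_len(n_peptides)),
    scan = denovo$Scan,
    taxid = sampled$sp, species = lin$species, family = lin$family,
    original = errored$original, altered = errored$altered,
    error_type = errored$error_type, changed = errored$changed
  )
  if (!is.null(csv)) readr::write_csv(denovo, csv, progress = FALSE)
  list(denovo = denovo, truth = truth, csv = csv)
}
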