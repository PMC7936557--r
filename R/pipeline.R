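#' The bundled Guanzhong Han 22-locus frequency table
#'
#' Reads the packaged transcription of the published allele-frequency
#' table (22 autosomal STR loci, 590 unrelated individuals, 2N = 1180).
#' One D6S477 allele label in the transcription is inferred; see the
#' fixture header comments for the note.
#'
#' @return a `freq_table`.
#' @export
load_guanzhong_freqs <- function() {
  path <- system.file("extdata", "guanzhong_han_table1.csv",
                      package = "strpopgen")
  if (path == "") stop("bundled frequency table not found")
  read_freq_table(path)
}

#' The 15-locus panel shared with the reference groups
#'
#' Locus panel used for all between-population comparisons (distances,
#' differentiation tests, MDS, PCA): the subset of the 22 typed loci
#' that the published reference groups also report.
#'
#' @return character vector of 15 locus names.
#' @export
guanzhong_shared_panel <- function() {
  c("D1S1656", "D3S3045", "D4S2366", "D5S2500", "D6S477", "D7S3048",
    "D8S1132", "D10S1435", "D11S2368", "D13S325", "D14S608", "D15S659",
    "D17S1290", "D18S535", "D22-GATA198B05")
}

#' Allele census of a frequency table
#'
#' @param freqs a `freq_table`.
#' @return list with `per_locus` (named allele counts), `total`,
#'   `min_frequency`, `max_frequency`.
#' @export
allele_census <- function(freqs) {
  validate_freq_table(freqs)
  k <- vapply(freqs$loci, length, 1L)
  allf <- unlist(freqs$loci, use.names = FALSE)
  list(per_locus = k, total = sum(k),
       min_frequency = min(allf), max_frequency = max(allf))
}

#' Run the full analysis pipeline into a report directory
#'
#' Sequence: forensic summary (He/PIC from the frequency table, PE when
#' observed heterozygosities are supplied) and allele census; then, when
#' reference populations are given, Nei's DA matrix (PHYLIP square +
#' CSV), neighbor-joining Newick tree, classical MDS and PCA coordinate
#' CSVs on the shared locus panel. A manifest records the configuration;
#' timestamps are confined to it, so repeated runs with the same inputs
#' and seed produce byte-identical CSV outputs.
#'
#' @param freqs a `freq_table` or path to one.
#' @param outdir report directory (created if needed).
#' @param ho optional named vector of per-locus observed
#'   heterozygosities.
#' @param references optional list of reference `freq_table`s.
#' @param mds_dims,pca_dims ordination dimensions.
#' @param seed integer seed recorded in the manifest (the deterministic
#'   stages do not consume randomness).
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(freqs, outdir, ho = NULL, references = NULL,
                         mds_dims = 2L, pca_dims = 3L, seed = 1L) {
  if (is.character(freqs)) freqs <- read_freq_table(freqs)
  validate_freq_table(freqs)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  out <- function(f) file.path(outdir, f)

  fs <- forensic_summary(freqs = freqs, ho = ho)
  num <- vapply(fs, is.numeric, TRUE)
  fs_round <- fs
  fs_round[num] <- lapply(fs[num], function(v) round(v, 4))
  write.csv(fs_round, out("forensic_summary.csv"), row.names = FALSE,
            quote = FALSE)
  paths$forensic_summary <- out("forensic_summary.csv")

  cen <- allele_census(freqs)
  census_df <- data.frame(locus = names(cen$per_locus),
                          allele_count = as.integer(cen$per_locus))
  write.csv(census_df, out("allele_census.csv"), row.names = FALSE,
            quote = FALSE)
  paths$allele_census <- out("allele_census.csv")

  manifest <- list(package_version = as.character(packageVersion("strpopgen")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = seed,
                   population = freqs$population,
                   gene_copies = freqs$gene_copies,
                   n_loci = length(freqs$loci),
                   total_alleles = cen$total,
                   ho_supplied = !is.null(ho),
                   n_references = length(references))

  if (!is.null(references)) {
    pops <- c(list(freqs), references)
    panel <- shared_loci(pops)
    manifest$shared_panel <- panel
    da <- nei_da_matrix(pops, panel)
    write_distance_matrix(da, out("nei_da.phy"), "phylip")
    write_distance_matrix(da, out("nei_da.csv"), "csv")
    paths$da_phylip <- out("nei_da.phy")
    paths$da_csv <- out("nei_da.csv")

    tree <- neighbor_joining(da)
    write_newick(tree, out("nj_tree.nwk"))
    paths$nj_tree <- out("nj_tree.nwk")

    mds <- classical_mds(da, mds_dims)
    mdf <- data.frame(population = mds$labels, round(mds$coords, 6))
    names(mdf)[-1] <- paste0("dim", seq_len(mds_dims))
    write.csv(mdf, out("mds_coordinates.csv"), row.names = FALSE,
              quote = FALSE)
    paths$mds <- out("mds_coordinates.csv")
    manifest$mds_eigenvalues <- unname(mds$explained[seq_len(mds_dims)])

    pca <- pca_frequencies(pops, pca_dims, panel)
    pdf_ <- data.frame(population = pca$labels, round(pca$coords, 6))
    write.csv(pdf_, out("pca_coordinates.csv"), row.names = FALSE,
              quote = FALSE)
    paths$pca <- out("pca_coordinates.csv")
    manifest$pca_explained <-
      unname(pca$explained[seq_len(min(pca_dims, length(pca$explained)))])
  }

  comb <- attr(fs, "combined")
  if (!is.null(comb)) manifest$cpe <- comb$cpe
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  paths$manifest <- out("manifest.json")
  invisible(paths)
}
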