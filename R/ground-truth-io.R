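# Serialization of simulation outputs: counts as MatrixMarket triplets,
# metadata/genotypes as CSV, ground truth as JSON (lossless round trip).

#' Write ground truth to JSON
#'
#' @param truth a `ground_truth` object from [simulate_population()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(
    cell_cluster = as.list(truth$cell_cluster),
    cell_pseudotime = cbind(
      data.frame(cell_id = rownames(truth$cell_pseudotime)),
      as.data.frame(truth$cell_pseudotime, row.names = FALSE)
    ),
    lineages = truth$lineages,
    module_membership = as.list(truth$module_membership),
    module_dag = truth$module_dag,
    planted_drivers = as.list(truth$planted_drivers),
    dynamic_genes = truth$dynamic_genes,
    eqtl_truth = truth$eqtl_truth,
    coloc_genes = truth$coloc_genes,
    qc_outliers = as.list(truth$qc_outliers),
    t_start = as.list(truth$t_start),
    seg_len = truth$seg_len
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read ground truth written by [write_ground_truth()]
#'
#' @param path JSON path.
#' @return a `ground_truth` object.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  pt <- as.data.frame(obj$cell_pseudotime)
  mat <- as.matrix(pt[, setdiff(names(pt), "cell_id"), drop = FALSE])
  rownames(mat) <- pt$cell_id
  structure(list(
    cell_cluster = unlist(obj$cell_cluster),
    cell_pseudotime = mat,
    lineages = lapply(obj$lineages, unlist),
    module_membership = unlist(obj$module_membership),
    module_dag = lapply(obj$module_dag, as.data.frame),
    planted_drivers = unlist(obj$planted_drivers),
    dynamic_genes = as.data.frame(obj$dynamic_genes),
    eqtl_truth = as.data.frame(obj$eqtl_truth),
    coloc_genes = as.data.frame(obj$coloc_genes),
    qc_outliers = if (length(obj$qc_outliers)) unlist(obj$qc_outliers) else
      setNames(character(0), character(0)),
    t_start = unlist(obj$t_start),
    seg_len = obj$seg_len
  ), class = "ground_truth")
}

#' Write a full simulated dataset to a directory
#'
#' Writes the count matrix in 10x-style triplet format, sample covariates and
#' long-format genotype dosages as CSV, the marker map and gene annotation as
#' CSV, the latent space as CSV, and the ground truth as JSON.
#'
#' @param sim output of [simulate_population()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_counts(sim$counts, file.path(dir, "counts"))
  write.csv(sim$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  write_genotypes(sim$genotypes, dir)
  write.csv(data.frame(cell_id = rownames(sim$latent_space), sim$latent_space),
            file.path(dir, "latent_space.csv"), row.names = FALSE)
  write_ground_truth(sim$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Write genotypes as long-format CSV plus a marker map
#'
#' @param genotypes a `founder_genotypes` object.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_genotypes <- function(genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- genotypes$dosage
  long <- data.frame(
    sample_id = rep(dimnames(d)[[1]], times = dim(d)[2] * dim(d)[3]),
    marker = rep(rep(dimnames(d)[[2]], each = dim(d)[1]), times = dim(d)[3]),
    founder = rep(dimnames(d)[[3]], each = dim(d)[1] * dim(d)[2]),
    dosage = as.vector(d)
  )
  write.csv(long, file.path(dir, "genotypes.csv"), row.names = FALSE)
  write.csv(genotypes$marker_map, file.path(dir, "marker_map.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read genotypes written by [write_genotypes()]
#'
#' @param dir directory with `genotypes.csv` and `marker_map.csv`.
#' @return a `founder_genotypes` object.
#' @export
read_genotypes <- function(dir) {
  long <- read.csv(file.path(dir, "genotypes.csv"))
  map <- read.csv(file.path(dir, "marker_map.csv"))
  samples <- unique(long$sample_id)
  founders <- sort(unique(long$founder))
  d <- array(0, dim = c(length(samples), nrow(map), length(founders)),
             dimnames = list(samples, map$marker, founders))
  d[cbind(match(long$sample_id, samples), match(long$marker, map$marker),
          match(long$founder, founders))] <- long$dosage
  structure(list(dosage = d, marker_map = map, founder_labels = founders),
            class = "founder_genotypes")
}
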