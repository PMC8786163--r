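#' Hierarchical embedding aggregation
#'
#' Patch embeddings are averaged up the hierarchy patch -> image ->
#' donor -> gene. Gene-level vectors are computed hierarchically
#' (patch -> image -> gene-within-donor -> gene) so that donors
#' contributing many images do not dominate a gene's representation.
#'
#' @name aggregate
NULL

#' Average child embeddings to their parents
#'
#' Each output vector is the unweighted mean of its children's vectors;
#' output rows are the distinct parent ids in lexicographic order.
#'
#' @param emb an \code{\link{embedding_matrix}}.
#' @param grouping named character vector mapping each child id (names)
#'   to its parent id.
#' @param target_level level label recorded on the result.
#' @return an \code{\link{embedding_matrix}} at \code{target_level}.
#' @export
aggregate_mean <- function(emb, grouping, target_level) {
  ids <- rownames(emb)
  if (!all(ids %in% names(grouping)))
    stop_invalid("entities without a parent mapping: %s",
                 paste(utils::head(setdiff(ids, names(grouping))), collapse = ", "))
  parent <- grouping[ids]
  m <- rowsum(unclass(emb)[, , drop = FALSE], group = parent)
  counts <- as.vector(table(parent)[rownames(m)])
  m <- m / counts
  m <- m[order(rownames(m)), , drop = FALSE]
  embedding_matrix(m, target_level)
}

#' (gene, donor)-level embeddings
#'
#' One vector per (gene, donor) pair present in the data: patch
#' embeddings are first averaged to images, then images of the same
#' (gene, donor) pair are averaged (the hierarchical convention).
#'
#' @param emb patch-level \code{\link{embedding_matrix}}.
#' @param patch_table data.frame (patch_id, image_id).
#' @param image_table data.frame (image_id, gene_id, donor_id).
#' @return \code{\link{embedding_matrix}} at level \code{"gene_donor"};
#'   row names are \code{"<gene_id>|<donor_id>"}.
#' @export
gene_donor_embedding <- function(emb, patch_table, image_table) {
  p2i <- stats::setNames(patch_table$image_id, patch_table$patch_id)
  img_emb <- aggregate_mean(emb, p2i, "image")
  key <- stats::setNames(paste(image_table$gene_id, image_table$donor_id,
                               sep = "|"), image_table$image_id)
  if (!all(rownames(img_emb) %in% names(key)))
    stop_invalid("image_table does not cover all embedded images")
  aggregate_mean(img_emb, key, "gene_donor")
}

#' Gene-level embeddings (donor balanced)
#'
#' patch -> image -> gene-within-donor -> gene.
#'
#' @inheritParams gene_donor_embedding
#' @return \code{\link{embedding_matrix}} at level \code{"gene"}.
#' @export
gene_embedding <- function(emb, patch_table, image_table) {
  gd <- gene_donor_embedding(emb, patch_table, image_table)
  gene <- sub("\\|.*$", "", rownames(gd))
  aggregate_mean(gd, stats::setNames(gene, rownames(gd)), "gene")
}

#' Remove donor main effects from (gene, donor) embeddings
#'
#' Subtracts from each (gene, donor) vector the mean vector of that donor
#' across all of its genes. Donor-level nuisance (staining gain, section
#' quality) shifts every gene of a donor in the same direction; centering
#' removes this shared component while preserving gene-specific
#' deviations, and is the embedding-space analogue of removing a batch
#' (donor) fixed effect before per-gene association tests.
#'
#' @param emb a \code{"gene_donor"}-level \code{\link{embedding_matrix}}.
#' @return the centred \code{embedding_matrix}, same rows.
#' @export
donor_center <- function(emb) {
  if (!identical(embedding_level(emb), "gene_donor"))
    stop_invalid("donor_center expects a gene_donor-level embedding")
  donor <- sub("^.*\\|", "", rownames(emb))
  M <- unclass(emb)
  attr(M, "level") <- NULL
  counts <- table(donor)
  centers <- rowsum(M, donor) / as.vector(counts[sort(unique(donor))])
  embedding_matrix(M - centers[donor, , drop = FALSE], "gene_donor")
}

#' Donor-presence control matrix
#'
#' Binary gene x donor matrix: entry (g, d) = 1 iff any image of gene g
#' comes from donor d. Used as a control feature set to detect
#' donor-composition confounding in annotation prediction.
#'
#' @param image_table data.frame (image_id, gene_id, donor_id).
#' @return binary matrix, rows = genes (sorted), cols = donors (sorted).
#' @export
donor_presence_matrix <- function(image_table) {
  if (nrow(image_table) == 0) stop_invalid("empty image table")
  tab <- table(image_table$gene_id, image_table$donor_id)
  m <- (unclass(tab) > 0) * 1L
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}
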