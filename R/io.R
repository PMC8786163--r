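#' Readers and writers for pipeline artifacts
#'
#' Canonical on-disk formats: UTF-8 tab-separated tables with mandatory
#' headers, 8-bit grayscale PNG for images / masks / patches, and JSON
#' manifests recording seeds and configuration. Embedding tables carry
#' their aggregation level and dimension in a leading comment line.
#'
#' @name cli_io
NULL

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_invalid("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", "))
  df
}

#' Read / write the image table
#'
#' @param path TSV file path.
#' @return data.frame with image_id, gene_id, donor_id, region.
#' @export
read_image_table <- function(path) {
  df <- require_columns(read_tsv(path),
                        c("image_id", "gene_id", "donor_id", "region"),
                        "image table")
  if (anyDuplicated(df$image_id)) {
    dup <- df$image_id[duplicated(df$image_id)][1]
    stop_invalid("duplicated image_id '%s' in %s", dup, path)
  }
  df
}

#' @rdname read_image_table
#' @param df image table data.frame.
#' @export
write_image_table <- function(df, path) {
  require_columns(df, c("image_id", "gene_id", "donor_id", "region"),
                  "image table")
  write_tsv(df, path)
}

#' Read / write donor tables
#'
#' @param path TSV file path.
#' @export
read_donor_table <- function(path) {
  require_columns(read_tsv(path), c("donor_id", "diagnosis"), "donor table")
}

#' @rdname read_donor_table
#' @param df donor table data.frame.
#' @export
write_donor_table <- function(df, path) write_tsv(df, path)

#' Read gene annotations
#'
#' @param path TSV with columns gene_id, annotation_name, value.
#' @export
read_annotations <- function(path) {
  require_columns(read_tsv(path), c("gene_id", "annotation_name", "value"),
                  "annotation table")
}

#' Write / read an embedding matrix as TSV
#'
#' The first line is \code{# level=<level> dim=<d>}; then a header
#' (\code{id}, \code{V1..Vd}) and one row per entity. Round-trips are
#' lossless to full double precision.
#'
#' @param emb an \code{\link{embedding_matrix}}.
#' @param path TSV file path.
#' @export
write_embeddings <- function(emb, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# level=%s dim=%d", embedding_level(emb), ncol(emb)),
             con)
  df <- data.frame(id = rownames(emb), unclass(emb),
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- c("id", paste0("V", seq_len(ncol(emb))))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_embeddings
#' @return \code{read_embeddings}: the \code{\link{embedding_matrix}}.
#' @export
read_embeddings <- function(path) {
  first <- readLines(path, n = 1L)
  level <- sub("^#\\s*level=(\\S+).*$", "\\1", first)
  if (identical(level, first))
    stop_invalid("missing '# level=... dim=...' metadata line in %s", path)
  df <- read_tsv(path)
  require_columns(df, "id", "embedding table")
  if (anyDuplicated(df$id))
    stop_invalid("duplicated id in embedding table %s", path)
  m <- as.matrix(df[setdiff(names(df), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- df$id
  colnames(m) <- NULL
  embedding_matrix(m, level)
}

#' Write a grayscale image (or mask) as 8-bit PNG
#'
#' @param img matrix in [0,1] (masks: 0/1).
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
}

#' Read a PNG as a grayscale matrix in [0,1]
#'
#' @param path PNG path.
#' @export
read_image_png <- function(path) {
  luminance(png::readPNG(path))
}

#' Write a study bundle to a directory
#'
#' Lays out \code{images/*.png}, \code{masks/*.png},
#' \code{image_table.tsv}, \code{donor_table.tsv},
#' \code{annotation_table.tsv}, \code{phenotypes.tsv} and a
#' \code{manifest.json} recording the spec and seeds.
#'
#' @param study an \code{ish_study}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  for (iid in names(study$images)) {
    write_image_png(study$images[[iid]],
                    file.path(dir, "images", paste0(iid, ".png")))
    write_image_png(study$truth_masks[[iid]] * 1,
                    file.path(dir, "masks", paste0(iid, ".png")))
  }
  write_image_table(study$image_table, file.path(dir, "image_table.tsv"))
  write_donor_table(study$donor_table, file.path(dir, "donor_table.tsv"))
  write_tsv(study$annotation_table, file.path(dir, "annotation_table.tsv"))
  write_tsv(study$truth_phenotypes, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(
    list(tool = "ishreid", spec = unclass(study$spec),
         n_images = length(study$images)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle from a directory
#'
#' @param dir directory written by \code{\link{write_study}}.
#' @return a list with the same shape as \code{\link{generate_study}}
#'   output (truth phenotypes are included when present).
#' @export
read_study <- function(dir) {
  it <- read_image_table(file.path(dir, "image_table.tsv"))
  images <- list(); masks <- list()
  for (iid in it$image_id) {
    images[[iid]] <- read_image_png(file.path(dir, "images",
                                              paste0(iid, ".png")))
    mp <- file.path(dir, "masks", paste0(iid, ".png"))
    if (file.exists(mp)) masks[[iid]] <- read_image_png(mp) > 0.5
  }
  ph_path <- file.path(dir, "phenotypes.tsv")
  structure(list(
    images = images, image_table = it,
    donor_table = read_donor_table(file.path(dir, "donor_table.tsv")),
    annotation_table = read_annotations(file.path(dir,
                                                  "annotation_table.tsv")),
    truth_masks = masks,
    truth_phenotypes = if (file.exists(ph_path)) read_tsv(ph_path)
  ), class = "ish_study")
}
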