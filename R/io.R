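#' Read and write connectome matrices as delimited text
#'
#' Matrices are stored tab-delimited with a header row of region IDs;
#' numeric values are written with 17 significant digits so that a written
#' table read back reproduces the doubles bit-identically.
#'
#' @param x matrix-bearing object (\code{structural_connectome},
#'   \code{functional_connectome}, or plain matrix).
#' @param path file path.
#' @name connectome_io
NULL

write_matrix_tsv <- function(M, region_ids, path) {
  txt <- apply(M, 1L, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = "\t"))
  writeLines(c(paste(region_ids, collapse = "\t"), txt), path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  ids <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  M <- do.call(rbind, lapply(lines[-1L], function(l)
    as.numeric(strsplit(l, "\t", fixed = TRUE)[[1L]])))
  dimnames(M) <- list(ids, ids)
  M
}

#' @rdname connectome_io
#' @export
write_structural_connectome <- function(x, path) {
  stopifnot(inherits(x, "structural_connectome"))
  write_matrix_tsv(x$A, x$region_ids, path)
  invisible(path)
}

#' @rdname connectome_io
#' @export
read_structural_connectome <- function(path, coordinates = NULL,
                                       labels = NULL) {
  M <- read_matrix_tsv(path)
  structural_connectome(M, region_ids = rownames(M),
                        coordinates = coordinates, labels = labels)
}

#' @rdname connectome_io
#' @export
write_functional_connectome <- function(x, path) {
  stopifnot(inherits(x, "functional_connectome"))
  write_matrix_tsv(x$F, x$region_ids, path)
  invisible(path)
}

#' @rdname connectome_io
#' @export
read_functional_connectome <- function(path) {
  M <- read_matrix_tsv(path)
  functional_connectome(M, region_ids = rownames(M))
}

#' Region coordinate and label tables
#'
#' Coordinates are written as \code{region_id,x,y,z}; labels as
#' \code{region_id,network_name} (comma-separated, with header).
#'
#' @param sc a \code{structural_connectome} with the relevant metadata.
#' @param path file path.
#' @export
write_coordinates <- function(sc, path) {
  stopifnot(!is.null(sc$coordinates))
  df <- data.frame(region_id = sc$region_ids,
                   x = formatC(sc$coordinates[, 1L], digits = 17, format = "g"),
                   y = formatC(sc$coordinates[, 2L], digits = 17, format = "g"),
                   z = formatC(sc$coordinates[, 3L], digits = 17, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_coordinates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  M <- as.matrix(df[, c("x", "y", "z")])
  rownames(M) <- df$region_id
  M
}

#' @rdname write_coordinates
#' @export
write_labels <- function(sc, path) {
  stopifnot(!is.null(sc$labels))
  utils::write.csv(data.frame(region_id = sc$region_ids,
                              network_name = sc$labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coordinates
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$network_name, df$region_id)
}

#' Serialize synthetic ground truth as JSON
#'
#' @param ground_truth a \code{synthetic_ground_truth}.
#' @param path file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  stopifnot(inherits(ground_truth, "synthetic_ground_truth"))
  jsonlite::write_json(unclass(ground_truth), path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$band_weights <- as.matrix(x$band_weights)
  structure(x, class = "synthetic_ground_truth")
}

#' Write a coupling map as a two-column TSV (region_id, R)
#'
#' @param coupling a \code{coupling_map}.
#' @param path file path.
#' @export
write_coupling_map <- function(coupling, path) {
  stopifnot(inherits(coupling, "coupling_map"))
  writeLines(c("region_id\tR",
               paste(names(coupling$R),
                     formatC(coupling$R, digits = 17, format = "g"),
                     sep = "\t")),
             path)
  invisible(path)
}
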