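# All tables are plain TSV with `#`-prefixed metadata header lines
# ("# key: value"), so outputs are greppable and diffable. Doubles are
# written with 17 significant digits so write -> read round-trips exactly.

format_double_cols <- function(df) {
  dplyr::mutate(df, dplyr::across(
    dplyr::where(is.double),
    function(x) sprintf("%.17g", x)
  ))
}

write_tsv_with_header <- function(df, path, meta = list()) {
  meta <- c(list(package = paste0("mlbundle ",
                                  as.character(utils::packageVersion("mlbundle")))),
            meta)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  hdr <- vapply(names(meta), function(k)
    paste0("# ", k, ": ", paste(meta[[k]], collapse = " ")), character(1))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    chr <- format_double_cols(df)
    writeLines(do.call(paste, c(unname(as.list(chr)), sep = "\t")), con)
  }
  invisible(path)
}

read_header_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  keys <- sub("^# ([^:]+):.*$", "\\1", lines)
  vals <- sub("^# [^:]+: ?", "", lines)
  stats::setNames(as.list(vals), keys)
}

#' Write / read a structural-network edge list
#'
#' TSV columns `node_a`, `node_b`, `polarity` (+1/-1), 0-based node ids;
#' node count and any provided metadata in `#` header lines.
#'
#' @param net A `structural_network`.
#' @param path File path.
#' @param meta Named list of extra header fields (e.g. `seed`, `phi`).
#' @return `path` (write) or a `structural_network` (read), invisibly
#'   for the writer.
#' @export
write_edge_list <- function(net, path, meta = list()) {
  stopifnot(inherits(net, "structural_network"))
  write_tsv_with_header(net$edges, path, c(list(n_nodes = net$n), meta))
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  meta <- read_header_meta(path)
  edges <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           col_types = readr::cols(
                             node_a = readr::col_integer(),
                             node_b = readr::col_integer(),
                             polarity = readr::col_integer()))
  n <- if (!is.null(meta$n_nodes)) as.integer(meta$n_nodes) else
    max(edges$node_a, edges$node_b) + 1L
  new_structural_network(n, edges)
}

#' Write / read a sample-by-feature matrix
#'
#' TSV with a header row of feature ids (`f0..f{n-1}` by default), one
#' row per sample; values round-trip exactly.
#'
#' @param S Numeric matrix (rows = samples).
#' @param path File path.
#' @param meta Named list of extra header fields.
#' @return `path`, or the matrix for the reader.
#' @export
write_feature_matrix <- function(S, path, meta = list()) {
  S <- as.matrix(S)
  if (is.null(colnames(S))) colnames(S) <- paste0("f", seq_len(ncol(S)) - 1L)
  write_tsv_with_header(tibble::as_tibble(S), path, meta)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  # base strtod parsing is correctly rounded, so %.17g output reads back
  # bit-identical (readr's fast parser can be one ulp off)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  M <- as.matrix(df)
  rownames(M) <- NULL
  M
}

#' Write / read a square score matrix (H, L, LH, or affinity)
#'
#' TSV with bundle/feature ids as both the header row and a leading `id`
#' column.
#'
#' @param M Square numeric matrix.
#' @param path File path.
#' @param meta Named list of extra header fields.
#' @return `path`, or the matrix for the reader.
#' @export
write_matrix_tsv <- function(M, path, meta = list()) {
  M <- as.matrix(M)
  ids <- rownames(M) %||% as.character(seq_len(nrow(M)))
  df <- tibble::as_tibble(M, .name_repair = "minimal")
  names(df) <- colnames(M) %||% ids
  df <- dplyr::bind_cols(tibble::tibble(id = ids), df)
  write_tsv_with_header(df, path, meta)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  rownames(M) <- as.character(df[[1]])
  M
}

#' Write a bundle-network edge list
#'
#' TSV `bundle_a  bundle_b  method`.
#'
#' @param net A `bundle_network`.
#' @param path File path.
#' @param meta Named list of extra header fields.
#' @return `path`, or a `bundle_network` for the reader.
#' @export
write_bundle_network <- function(net, path, meta = list()) {
  stopifnot(inherits(net, "bundle_network"))
  write_tsv_with_header(tidy.bundle_network(net), path,
                        c(list(n_bundles = net$n_nodes), meta))
}

#' @rdname write_bundle_network
#' @export
read_bundle_network <- function(path) {
  meta <- read_header_meta(path)
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(
                          bundle_a = readr::col_integer(),
                          bundle_b = readr::col_integer(),
                          method = readr::col_character()))
  new_bundle_network(as.integer(meta$n_bundles),
                     df[, c("bundle_a", "bundle_b")],
                     if (nrow(df) > 0) df$method[1] else meta$method %||% "score")
}
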