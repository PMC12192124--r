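# File formats. All delimited output is tab-separated with '.' decimals
# and a header row; the delimiter of inputs is taken from the extension
# (.csv -> comma, anything else -> tab).

io_delim <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a time-series expression table
#'
#' Two layouts are accepted. Long format: one delimited file with columns
#' `cell_id`, `time`, then one numeric column per gene. Manifest format:
#' a two-column file (`file`, `time`) pointing at one cells x genes
#' matrix file per time point (paths relative to the manifest). Validation
#' is strict: NA, negative values and duplicate cell ids within a time
#' point are hard errors naming the offending row/column.
#'
#' @param path path to a TSV/CSV file
#' @return a [ts_expression()] object (times sorted increasing; gene
#'   order from the header)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = io_delim(path), check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (identical(sort(names(df)), sort(c("file", "time"))))
    return(read_expression_manifest(df, dirname(path)))
  if (!all(c("cell_id", "time") %in% names(df)))
    stop("expected columns `cell_id` and `time` (or a file/time manifest)")
  genes <- setdiff(names(df), c("cell_id", "time"))
  if (length(genes) < 2L) stop("need at least 2 gene columns")
  for (g in genes) {
    v <- df[[g]]
    if (!is.numeric(v)) stop("gene column `", g, "` is not numeric")
    if (anyNA(v))
      stop("NA in gene `", g, "` at row ", which(is.na(v))[1L])
    if (any(v < 0))
      stop("negative value in gene `", g, "` at row ", which(v < 0)[1L])
  }
  if (anyNA(df$time)) stop("NA in `time` column")
  times <- sort(unique(df$time))
  mats <- lapply(times, function(tp) {
    sub <- df[df$time == tp, , drop = FALSE]
    if (anyDuplicated(sub$cell_id))
      stop("duplicate cell_id `", sub$cell_id[duplicated(sub$cell_id)][1L],
           "` at time ", tp)
    x <- as.matrix(sub[, genes, drop = FALSE])
    rownames(x) <- sub$cell_id
    x
  })
  ts_expression(mats, times, genes)
}

read_expression_manifest <- function(df, dir) {
  mats <- lapply(df$file, function(f) {
    p <- if (file.exists(f)) f else file.path(dir, f)
    if (!file.exists(p)) stop("matrix file not found: ", f)
    as.matrix(utils::read.delim(p, sep = io_delim(p), check.names = FALSE))
  })
  ord <- order(df$time)
  ts_expression(mats[ord], df$time[ord])
}

#' Write a time-series expression table (long format)
#'
#' @param data a [ts_expression()] object
#' @param path output file path (`.csv` for comma-separated, otherwise
#'   tab-separated)
#' @return `path`, invisibly
#' @export
write_expression <- function(data, path) {
  stopifnot(inherits(data, "ts_expression"))
  rows <- lapply(seq_along(data$times), function(i) {
    x <- data$matrices[[i]]
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("t", i, "_c", seq_len(nrow(x)))
    data.frame(cell_id = ids, time = data$times[i], x,
               check.names = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = io_delim(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signed gold-standard edge list
#'
#' Expects a delimited file with columns `regulator`, `target`, `sign`
#' where sign is one of `1`, `-1`, `+`, `-`. Self-edges and duplicate
#' edges with conflicting signs are rejected.
#'
#' @param path path to the edge-list file
#' @param genes optional full gene universe; defaults to the genes seen
#'   in the edge list
#' @return a `grn` object
#' @export
read_gold_standard <- function(path, genes = NULL) {
  df <- utils::read.delim(path, sep = io_delim(path),
                          stringsAsFactors = FALSE)
  if (!all(c("regulator", "target", "sign") %in% names(df)))
    stop("expected columns regulator, target, sign")
  sgn <- as.character(df$sign)
  ok <- sgn %in% c("1", "+1", "+", "-1", "-")
  if (!all(ok))
    stop("invalid sign `", sgn[!ok][1L], "` (use +1/-1 or +/-)")
  df$sign <- ifelse(sgn %in% c("1", "+1", "+"), 1, -1)
  if (any(df$regulator == df$target))
    stop("self-edge on `", df$regulator[df$regulator == df$target][1L],
         "`: self-regulation is excluded")
  key <- paste(df$regulator, df$target)
  if (anyDuplicated(key)) {
    agg <- tapply(df$sign, key, function(s) length(unique(s)))
    if (any(agg > 1))
      stop("conflicting signs for duplicated edge: ",
           names(agg)[agg > 1][1L])
    df <- df[!duplicated(key), ]
  }
  if (is.null(genes)) genes <- sort(unique(c(df$regulator, df$target)))
  rownames(df) <- NULL
  structure(list(genes = genes,
                 edges = df[, c("regulator", "target", "sign")]),
            class = "grn")
}

#' Write a signed edge list
#'
#' @param grn a `grn` object
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_gold_standard <- function(grn, path) {
  stopifnot(inherits(grn, "grn"))
  utils::write.table(grn$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a dynamic-network fit to a directory
#'
#' Emits, per window, a signed edge list
#' (`window_<k>_edges.tsv`: regulator, target, weight, sign — nonzero
#' adjacency entries only) and a GraphML file; plus one combined JSON
#' with the full numeric matrices (round-trippable via
#' [read_networks()]) and a run manifest echoing the configuration.
#'
#' @param result an `fdygrn` fit
#' @param out_dir output directory (created if missing)
#' @return character vector of written paths, invisibly
#' @export
write_networks <- function(result, out_dir) {
  stopifnot(inherits(result, "fdygrn"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  paths <- character(0)
  for (w in result$windows) {
    el <- window_predictions(w)
    names(el)[names(el) == "score"] <- "weight"
    p <- file.path(out_dir, sprintf("window_%d_edges.tsv", w$window_index))
    utils::write.table(el, p, sep = "\t", quote = FALSE, row.names = FALSE)
    g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                       vertices = result$genes)
    pg <- file.path(out_dir, sprintf("window_%d.graphml", w$window_index))
    igraph::write_graph(g, pg, format = "graphml")
    paths <- c(paths, p, pg)
  }
  pj <- file.path(out_dir, "networks.json")
  jsonlite::write_json(list(
    genes = result$genes, config = result$config,
    windows = lapply(result$windows, function(w) list(
      window_index = w$window_index, interval_pair = w$interval_pair,
      alpha = w$alpha, sign = w$sign, adjacency = w$adjacency))
  ), pj, digits = NA, auto_unbox = TRUE)
  pm <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    package = "fdygrn",
    version = as.character(utils::packageVersion("fdygrn")),
    config = result$config, written = format(Sys.time(), tz = "UTC"),
    outputs = basename(c(paths, pj))
  ), pm, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, pj, pm))
}

#' Read back a combined networks JSON
#'
#' Reconstructs an `fdygrn` object from the `networks.json` written by
#' [write_networks()].
#'
#' @param path path to `networks.json`
#' @return an `fdygrn` object
#' @export
read_networks <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- j$genes
  fix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(genes, genes)
    m
  }
  windows <- lapply(seq_len(nrow(j$windows)), function(i) list(
    window_index = j$windows$window_index[i],
    interval_pair = j$windows$interval_pair[[i]],
    alpha = fix(j$windows$alpha[[i]]),
    sign = fix(j$windows$sign[[i]]),
    adjacency = fix(j$windows$adjacency[[i]])))
  structure(list(windows = windows, genes = genes,
                 config = as.list(j$config), call = NULL),
            class = "fdygrn")
}
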