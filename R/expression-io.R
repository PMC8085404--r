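#' Read a NanoString RCC count file
#'
#' RCC is the per-sample deliverable of the NanoString nCounter platform: a
#' sectioned text file whose `<Code_Summary>` block holds one CSV record per
#' probe (`CodeClass,Name,Accession,Count`). Only the `Endogenous` and
#' `Housekeeping` code classes are panel genes; positive/negative/binding
#' controls are dropped.
#'
#' @param path Path to one `.RCC` file (one sample).
#' @param sample_id Column name for the sample; defaults to the file name
#'   without extension.
#' @return A tibble with a `gene` column and one count column per file,
#'   carrying attribute `platform = "COUNTS"`.
#' @seealso [merge_expression()] to combine several single-sample reads.
#' @export
read_rcc <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("RCC file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[Rr][Cc][Cc]$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  open <- grep("^<Code_Summary>", lines)
  close <- grep("^</Code_Summary>", lines)
  if (length(open) != 1L || length(close) != 1L || close <= open) {
    stop("RCC format error: no <Code_Summary> section in ", path, call. = FALSE)
  }
  body <- lines[(open + 1L):(close - 1L)]
  body_lineno <- (open + 1L):(close - 1L)
  keep <- nzchar(trimws(body))
  body <- body[keep]; body_lineno <- body_lineno[keep]
  # drop the CodeClass,Name,Accession,Count header if present
  if (length(body) && grepl("^CodeClass", body[1L])) {
    body <- body[-1L]; body_lineno <- body_lineno[-1L]
  }
  if (!length(body)) stop("RCC format error: empty Code_Summary in ", path, call. = FALSE)
  fields <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("RCC parse error at line ", body_lineno[which(nf < 4L)[1L]],
         ": expected CodeClass,Name,Accession,Count", call. = FALSE)
  }
  code_class <- vapply(fields, `[[`, "", 1L)
  gene <- vapply(fields, `[[`, "", 2L)
  count_chr <- vapply(fields, `[[`, "", 4L)
  count <- suppressWarnings(as.numeric(count_chr))
  bad <- which(!is.finite(count))
  if (length(bad)) {
    stop("RCC parse error: non-numeric Count '", count_chr[bad[1L]],
         "' at line ", body_lineno[bad[1L]], " of ", path, call. = FALSE)
  }
  if (any(count < 0)) {
    stop("RCC parse error: negative Count at line ",
         body_lineno[which(count < 0)[1L]], " of ", path, call. = FALSE)
  }
  keep_class <- tolower(code_class) %in% c("endogenous", "housekeeping")
  gene <- gene[keep_class]; count <- count[keep_class]
  if (anyDuplicated(gene)) {
    stop("RCC parse error: duplicate gene name ",
         gene[duplicated(gene)][1L], " in ", path, call. = FALSE)
  }
  out <- tibble::tibble(gene = gene, !!sample_id := count)
  attr(out, "platform") <- "COUNTS"
  out
}

#' Merge single-sample expression tables by gene name
#'
#' @param ... Tibbles as returned by [read_rcc()] (or a single list of them).
#' @return One tibble with a `gene` column and one column per sample. Genes
#'   must agree across inputs (order may differ).
#' @export
merge_expression <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  stopifnot(length(tabs) >= 1L)
  ref <- sort(tabs[[1L]]$gene)
  for (t in tabs) {
    if (!identical(sort(t$gene), ref)) {
      stop("cannot merge: gene sets differ across samples", call. = FALSE)
    }
  }
  out <- purrr::reduce(tabs, dplyr::inner_join, by = "gene")
  attr(out, "platform") <- attr(tabs[[1L]], "platform")
  out
}

#' Read / write a tab-delimited expression matrix
#'
#' Plain TSV with genes in rows: first column gene names, header row sample
#' identifiers. Values must be finite and non-negative (raw counts or
#' FPKM-UQ). Lines starting with `#` are treated as provenance comments and
#' skipped.
#'
#' @param path File path.
#' @param platform `"COUNTS"` or `"FPKM_UQ"`; stored as an attribute.
#' @return `read_matrix()` returns a tibble with a `gene` column and one
#'   numeric column per sample; `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, platform = c("COUNTS", "FPKM_UQ")) {
  platform <- match.arg(platform)
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 2L) stop("matrix file needs a header and at least one gene row", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1L]]
  samples <- header[-1L]
  if (!length(samples)) stop("matrix file has no sample columns", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids in header", call. = FALSE)
  rows <- parts[-1L]
  if (any(lengths(rows) != length(header))) {
    stop("ragged row in matrix file (wrong number of fields)", call. = FALSE)
  }
  gene <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(gene)) {
    stop("duplicate gene name in matrix file: ",
         gene[duplicated(gene)][1L], call. = FALSE)
  }
  vals <- vapply(rows, function(r) suppressWarnings(as.numeric(r[-1L])),
                 numeric(length(samples)))
  vals <- matrix(vals, nrow = length(samples))  # samples x genes
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("non-numeric or non-finite expression value in matrix file", call. = FALSE)
  }
  if (any(vals < 0)) stop("negative expression value in matrix file", call. = FALSE)
  out <- tibble::tibble(gene = gene)
  for (j in seq_along(samples)) out[[samples[j]]] <- vals[j, ]
  attr(out, "platform") <- platform
  out
}

#' @rdname read_matrix
#' @param data Tibble with a `gene` column and numeric sample columns.
#' @param header Optional character vector of `#`-prefixed provenance lines
#'   written above the table.
#' @export
write_matrix <- function(data, path, header = NULL) {
  check_expression(data)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", sub("^#\\s*", "", header)), con)
  writeLines(paste(names(data), collapse = "\t"), con)
  vals <- as.matrix(data[, -1L, drop = FALSE])
  body <- vapply(seq_len(nrow(data)), function(i) {
    paste(c(data$gene[i], format(vals[i, ], trim = TRUE, digits = 15)), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

check_expression <- function(data, arg = "data") {
  if (!is.data.frame(data) || !"gene" %in% names(data)) {
    stop("`", arg, "` must be a data frame with a `gene` column", call. = FALSE)
  }
  if (ncol(data) < 2L) stop("`", arg, "` has no sample columns", call. = FALSE)
  if (anyDuplicated(data$gene)) stop("duplicate gene names in `", arg, "`", call. = FALSE)
  vals <- as.matrix(data[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("sample columns of `", arg, "` must be numeric", call. = FALSE)
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("`", arg, "` contains missing or non-finite values", call. = FALSE)
  }
  invisible(data)
}

#' Read / write per-sample subtype labels
#'
#' Two-column TSV (`sample_id`, `label`) with labels among
#' `LUAD`, `LUSC`, `NOS`, `UNKNOWN`. `#` comment lines are skipped.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id` and `label`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("label file needs `sample_id` and `label` columns", call. = FALSE)
  }
  bad <- setdiff(unique(df$label), c("LUAD", "LUSC", "NOS", "UNKNOWN"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  tibble::as_tibble(df[, c("sample_id", "label")])
}

#' @rdname read_labels
#' @param labels Tibble with columns `sample_id` and `label`.
#' @param header Optional `#`-prefixed provenance lines.
#' @export
write_labels <- function(labels, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", sub("^#\\s*", "", header)), con)
  writeLines("sample_id\tlabel", con)
  writeLines(paste(labels$sample_id, labels$label, sep = "\t"), con)
  invisible(path)
}
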