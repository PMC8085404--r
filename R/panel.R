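#' Construct a gene panel
#'
#' A gene panel assigns each gene on a targeted expression panel a role:
#' `"LUAD"` (adenocarcinoma-associated), `"LUSC"` (squamous-cell-associated),
#' or `"HOUSEKEEPING"` (stable reference genes used only for per-sample
#' normalization). The two tumour-associated roles together form the
#' *diagnostic* genes the classifier may use.
#'
#' @param genes A data frame with columns `gene` (character, unique,
#'   non-empty) and `role` (one of `"LUAD"`, `"LUSC"`, `"HOUSEKEEPING"`).
#'
#' @return A tibble of class `gene_panel` with columns `gene` and `role`.
#' @examples
#' gene_panel(data.frame(
#'   gene = c("NKX2-1", "TP63", "ACTB"),
#'   role = c("LUAD", "LUSC", "HOUSEKEEPING")
#' ))
#' @export
gene_panel <- function(genes) {
  if (!is.data.frame(genes) || !all(c("gene", "role") %in% names(genes))) {
    stop("`genes` must be a data frame with columns `gene` and `role`", call. = FALSE)
  }
  panel <- tibble::tibble(
    gene = as.character(genes$gene),
    role = as.character(genes$role)
  )
  validate_gene_panel(panel)
  class(panel) <- c("gene_panel", class(tibble::tibble()))
  panel
}

panel_roles <- c("LUAD", "LUSC", "HOUSEKEEPING")

validate_gene_panel <- function(panel) {
  if (anyNA(panel$gene) || any(!nzchar(panel$gene))) {
    stop("panel gene names must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(panel$gene)) {
    dup <- unique(panel$gene[duplicated(panel$gene)])
    stop("duplicate panel gene names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(panel$role), panel_roles)
  if (length(bad)) {
    stop("unknown panel roles: ", paste(bad, collapse = ", "),
         " (expected LUAD, LUSC or HOUSEKEEPING)", call. = FALSE)
  }
  if (!any(panel$role == "HOUSEKEEPING")) {
    stop("panel must contain at least one HOUSEKEEPING gene", call. = FALSE)
  }
  if (!any(panel$role != "HOUSEKEEPING")) {
    stop("panel must contain at least one diagnostic (LUAD or LUSC) gene", call. = FALSE)
  }
  invisible(panel)
}

#' Extract gene names from a panel by role
#'
#' @param panel A [gene_panel()].
#' @param roles Character vector of roles to keep. The default selects the
#'   diagnostic genes (everything except housekeeping).
#' @return Character vector of gene names, in panel order.
#' @export
panel_genes <- function(panel, roles = c("LUAD", "LUSC")) {
  validate_gene_panel(panel)
  panel$gene[panel$role %in% roles]
}

#' Read / write a gene panel as JSON
#'
#' The on-disk format is a JSON object with a `genes` array of
#' `{name, role}` records.
#'
#' @param path File path.
#' @return `read_panel()` returns a [gene_panel()]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$genes)) stop("panel file lacks a `genes` field: ", path, call. = FALSE)
  g <- obj$genes
  if (!all(c("name", "role") %in% names(g))) {
    stop("panel `genes` records need `name` and `role` fields", call. = FALSE)
  }
  gene_panel(data.frame(gene = g$name, role = g$role))
}

#' @rdname read_panel
#' @param panel A [gene_panel()].
#' @export
write_panel <- function(panel, path) {
  validate_gene_panel(panel)
  jsonlite::write_json(
    list(genes = data.frame(name = panel$gene, role = panel$role)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
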