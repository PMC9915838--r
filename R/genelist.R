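# Gene lists --------------------------------------------------------------

#' Construct a gene list
#'
#' @param symbols Character vector of gene symbols; duplicates are removed,
#'   empty symbols are an error.
#' @param name Display name of the list (e.g. a panel identifier).
#' @param provenance One of `panelapp_green`, `gencc_strong_definitive`,
#'   `custom`.
#' @param allow_empty Permit a list with no symbols (useful for
#'   restriction to nothing); reading an empty list from file is always
#'   fatal.
#' @return An object of class `gene_list`.
#' @export
gene_list <- function(symbols, name = "genes",
                      provenance = c("custom", "panelapp_green",
                                     "gencc_strong_definitive"),
                      allow_empty = FALSE) {
  provenance <- match.arg(provenance)
  symbols <- unique(as.character(symbols))
  if (length(symbols) == 0 && !allow_empty)
    stop("gene list '", name, "' is empty")
  if (any(is.na(symbols) | !nzchar(symbols)))
    stop("gene list '", name, "' contains empty symbols")
  structure(list(name = name, symbols = symbols, provenance = provenance),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat("<gene_list '", x$name, "' (", x$provenance, "): ",
      length(x$symbols), " genes>\n", sep = "")
  invisible(x)
}

#' Read a gene list from TSV
#'
#' One gene symbol per row with an optional classification column. For
#' `gencc_strong_definitive` provenance only rows classified Strong or
#' Definitive are kept; for `panelapp_green` only rows rated green. An
#' empty result is fatal.
#'
#' @param path TSV path. A header row is expected.
#' @param provenance List provenance; drives the classification filter.
#' @param symbol_col,class_col Column names or indices; `class_col` defaults
#'   to the second column when a classification filter applies.
#' @param name List name; defaults to the file name.
#' @return A [gene_list()] object.
#' @export
read_gene_list <- function(path,
                           provenance = c("custom", "panelapp_green",
                                          "gencc_strong_definitive"),
                           symbol_col = 1, class_col = NULL,
                           name = NULL) {
  provenance <- match.arg(provenance)
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, quote = "",
                   comment.char = "#")
  if (nrow(df) == 0) stop("gene list file is empty: ", path)
  symbols <- as.character(df[[symbol_col]])
  if (provenance != "custom") {
    if (is.null(class_col)) {
      if (ncol(df) < 2)
        stop("classification column required for ", provenance,
             " provenance: ", path)
      class_col <- 2
    }
    cls <- tolower(as.character(df[[class_col]]))
    keep <- switch(provenance,
      gencc_strong_definitive = cls %in% c("strong", "definitive"),
      panelapp_green = cls %in% c("green", "3")
    )
    symbols <- symbols[keep]
    if (length(symbols) == 0)
      stop("no genes pass the ", provenance, " classification filter: ",
           path)
  }
  gene_list(symbols, name = if (is.null(name)) basename(path) else name,
            provenance = provenance)
}

# Union of green genes over one or more panels; names the triggering panel.
panel_union <- function(panels) {
  if (inherits(panels, "gene_list")) panels <- list(panels)
  if (length(panels) == 0)
    return(data.frame(gene = character(), panel = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(panels, function(p) {
    data.frame(gene = p$symbols,
               panel = rep_len(p$name, length(p$symbols)),
               stringsAsFactors = FALSE)
  }))
  out[!duplicated(out$gene), , drop = FALSE]
}
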