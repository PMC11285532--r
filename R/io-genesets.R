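# gene-set collections and GMT IO

#' Construct a gene-set collection
#'
#' A named list of uppercase gene-symbol vectors with a category label.
#'
#' @param sets Named list of character vectors (genes). Names must be unique,
#'   every set non-empty; symbols are uppercased.
#' @param category One of `"pathway"`, `"drug"`, `"marker_reference"`,
#'   `"disease_deg"`, `"gwas"`.
#' @return An object of class `rv_genesets`.
#' @export
gene_sets <- function(sets, category = c("pathway", "drug", "marker_reference",
                                         "disease_deg", "gwas")) {
  category <- match.arg(category)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("all sets must be named")
  }
  if (anyDuplicated(names(sets))) {
    abort(paste0("duplicate set name: ",
                 names(sets)[duplicated(names(sets))][1]))
  }
  sets <- lapply(sets, function(g) unique(norm_symbols(g)))
  if (any(lengths(sets) == 0)) abort("empty gene set")
  structure(list(sets = sets, category = category), class = "rv_genesets")
}

#' @export
print.rv_genesets <- function(x, ...) {
  cat(sprintf("<rv_genesets> %d %s set(s); sizes %s\n",
              length(x$sets), x$category,
              paste(range(lengths(x$sets)), collapse = "-")))
  invisible(x)
}

#' @export
length.rv_genesets <- function(x) length(x$sets)

#' Tidy a gene-set collection into long format
#'
#' @param x An `rv_genesets` object.
#' @param ... Unused.
#' @return Tibble with columns `set`, `gene`, `category`.
#' @export
tidy.rv_genesets <- function(x, ...) {
  tibble(set = rep(names(x$sets), lengths(x$sets)),
         gene = unlist(x$sets, use.names = FALSE),
         category = x$category)
}

#' Read a GMT file
#'
#' Standard GMT: tab-separated `name`, `description`, then genes. Gene symbols
#' are uppercased; duplicate set names and empty gene lists are rejected.
#'
#' @param path GMT file path.
#' @inheritParams gene_sets
#' @return An `rv_genesets` object.
#' @export
read_gmt <- function(path, category = "pathway") {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  nms <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate set name: ", nms[duplicated(nms)][1]))
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nms
  gene_sets(sets, category = category)
}

#' Write a gene-set collection as GMT
#'
#' @param gs An `rv_genesets` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(nm) {
    paste(c(nm, gs$category, gs$sets[[nm]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, path)
  invisible(path)
}
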