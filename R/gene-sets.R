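#' Construct a gene set
#'
#' A gene set is a named, ordered collection of unique gene symbols, the unit
#' of input for signature scoring (e.g. the luminal and basal halves of the
#' BASE47 bladder-cancer subtype panel, a Macro-C3 immunosuppressive-macrophage
#' signature, or a T-cell cytotoxicity signature).
#'
#' @param name Non-empty set name.
#' @param genes Character vector of at least two unique gene symbols.
#' @param description Optional free-text description (kept through GMT
#'   round-trips).
#' @return An object of class `gene_set`: a list with elements `name`,
#'   `genes` and `description`.
#' @examples
#' gene_set("cytotoxicity", c("GZMB", "PRF1", "GZMA"))
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("gene set 'name' must be a non-empty string", call. = FALSE)
  }
  genes <- as.character(genes)
  if (length(genes) < 2L) {
    stop(sprintf("gene set '%s' must contain at least 2 genes", name),
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop(sprintf("gene set '%s' contains duplicated gene symbols", name),
         call. = FALSE)
  }
  if (any(!nzchar(genes))) {
    stop(sprintf("gene set '%s' contains empty gene symbols", name),
         call. = FALSE)
  }
  structure(
    list(name = name, genes = genes,
         description = as.character(description)[1L]),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes", x$name, length(x$genes)))
  if (nzchar(x$description)) cat(sprintf(" (%s)", x$description))
  cat("\n  ", paste(utils::head(x$genes, 8L), collapse = ", "))
  if (length(x$genes) > 8L) cat(", ...")
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Lines with fewer than three
#' fields and duplicated set names are errors, not silently skipped, because a
#' malformed signature file silently changes every downstream score.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set] objects.
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("GMT file not found: '%s'", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty", call. = FALSE)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d field(s); need >= 3 (name, description, genes)",
                   i, length(fields)), call. = FALSE)
    }
    sets[[i]] <- gene_set(fields[1L], fields[-(1:2)], description = fields[2L])
  }
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicated gene-set name(s) in GMT: %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set] or list of them.
#' @param path Output path.
#' @return `path`, invisibly. `read_gmt(write_gmt(sets, path))` recovers the
#'   sets exactly, including descriptions.
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (!length(sets) || !all(vapply(sets, inherits, logical(1), "gene_set"))) {
    stop("'sets' must be a gene_set or a list of gene_set objects",
         call. = FALSE)
  }
  nm <- vapply(sets, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    stop("cannot write GMT with duplicated set names", call. = FALSE)
  }
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
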