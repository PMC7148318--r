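#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member genes. Duplicate genes within a line are removed (first
#' occurrence kept) with a warning; gene order is otherwise preserved.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors, one per set, with set
#'   descriptions in `attr(, "descriptions")`. An empty file yields an empty
#'   list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  descs <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d has %d field(s); need name, description, and at least one gene",
                    i, length(f)))
    }
    nms[i] <- f[1]
    descs[i] <- f[2]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("duplicate genes in set '%s' (GMT line %d); keeping first occurrences",
                   f[1], i))
      genes <- genes[!duplicated(genes)]
    }
    if (length(genes) == 0) abort(sprintf("set '%s' (GMT line %d) is empty", f[1], i))
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate set name in GMT: ", nms[duplicated(nms)][1]))
  }
  names(sets) <- nms
  names(descs) <- nms
  structure(sets, descriptions = descs)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors (set name -> genes), e.g. from
#'   [read_gmt()] or [as_gene_sets()].
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions;
#'   defaults to the `descriptions` attribute or `"na"`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("every gene set must be named")
  }
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
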