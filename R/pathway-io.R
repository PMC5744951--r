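#' Pathway with activator/repressor gene roles
#'
#' A pathway maps genes to their activator/repressor role (ARR): +1 full
#' activator, +0.5 partial activator, 0 neutral, -0.5 partial repressor,
#' -1 full repressor.
#'
#' @param pathway_id pathway identifier.
#' @param roles named numeric vector, gene -> ARR; values restricted to
#'   \{-1, -0.5, 0, 0.5, 1\}; one entry per gene.
#' @return an object of class `pathway`.
#' @export
pathway <- function(pathway_id, roles) {
  if (!length(roles)) stop("a pathway needs at least one gene", call. = FALSE)
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("'roles' must be a named vector (gene -> ARR)", call. = FALSE)
  dup <- unique(names(roles)[duplicated(names(roles))])
  if (length(dup))
    stop(sprintf("duplicate gene(s) in pathway '%s': %s", pathway_id,
                 paste(dup, collapse = ", ")), call. = FALSE)
  bad <- !roles %in% c(-1, -0.5, 0, 0.5, 1)
  if (any(bad))
    stop(sprintf("ARR value(s) outside {-1,-0.5,0,0.5,1} in pathway '%s': %s",
                 pathway_id, paste(roles[bad], collapse = ", ")), call. = FALSE)
  structure(list(pathway_id = as.character(pathway_id),
                 roles = roles), class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat(sprintf("pathway '%s': %d gene(s), %d activator(s), %d repressor(s)\n",
              x$pathway_id, length(x$roles), sum(x$roles > 0),
              sum(x$roles < 0)))
  invisible(x)
}

#' Read pathway role tables
#'
#' TSV with header and columns `pathway_id`, `gene_id`, `ARR`. A gene may
#' appear in several pathways but only once within a pathway.
#'
#' @param path file path.
#' @return named list of [pathway] objects, in order of first appearance.
#' @export
read_pathways <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "")
  need <- c("pathway_id", "gene_id", "ARR")
  if (!all(need %in% colnames(df)))
    stop("pathway file needs columns pathway_id, gene_id, ARR", call. = FALSE)
  df$pathway_id <- trimws(as.character(df$pathway_id))
  df$gene_id <- trimws(as.character(df$gene_id))
  ids <- unique(df$pathway_id)
  out <- lapply(ids, function(pid) {
    sub <- df[df$pathway_id == pid, ]
    pathway(pid, stats::setNames(as.numeric(sub$ARR), sub$gene_id))
  })
  stats::setNames(out, ids)
}

#' @rdname read_pathways
#' @param pathways list of [pathway] objects.
#' @export
write_pathways <- function(pathways, path) {
  rows <- do.call(rbind, lapply(pathways, function(p)
    data.frame(pathway_id = p$pathway_id, gene_id = names(p$roles),
               ARR = unname(p$roles), stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
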