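#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated as set id,
#' description, then member gene ids. Duplicate members within a set are
#' de-duplicated; an empty file yields an empty collection with a warning.
#'
#' @param path Path to a GMT file.
#' @param name Collection name (default: file name without extension).
#' @return Object of class `gene_set_collection`: `name` and `sets`, a
#'   named list of `list(description =, genes =)`.
#' @export
read_gmt <- function(path, name = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(name = name, sets = list()),
                     class = "gene_set_collection"))
  }
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("parse error in ", path, " line ", i,
           ": GMT lines need at least 3 tab-separated fields")
    }
    ids[i] <- fields[1]
    sets[[i]] <- list(description = fields[2], genes = unique(fields[-(1:2)]))
  }
  if (anyDuplicated(ids)) {
    stop("parse error in ", path, ": duplicate set id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  structure(list(name = name, sets = sets), class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param collection `gene_set_collection`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    paste(c(id, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection '", x$name, "': ", length(x$sets), " sets\n",
      sep = "")
  invisible(x)
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether a cluster contains more members of a gene set than
#' expected by drawing the cluster at random from the background:
#' `p = P(X >= x)` with `X ~ Hypergeometric(N, K, n)`, where `N` is the
#' background size, `K` the set size within the background, `n` the cluster
#' size, and `x` the observed overlap. Cluster and set are intersected with
#' the background first.
#'
#' @param cluster_genes Character vector of cluster members.
#' @param set_genes Character vector of gene-set members.
#' @param background Character vector, the gene universe.
#' @return List `x`, `n`, `K`, `N`, `fold_enrichment`, `p_value`.
#' @export
#' @examples
#' hypergeom_enrich(letters[1:5], letters[1:5], letters[1:10])$p_value
#' # = 1 / choose(10, 5)
hypergeom_enrich <- function(cluster_genes, set_genes, background) {
  background <- unique(background)
  N <- length(background)
  if (N == 0L) stop("input error: empty background")
  cl <- intersect(unique(cluster_genes), background)
  gs <- intersect(unique(set_genes), background)
  x <- length(intersect(cl, gs))
  n <- length(cl)
  K <- length(gs)
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  fold <- if (n > 0 && K > 0) (x / n) / (K / N) else NA_real_
  list(x = x, n = n, K = K, N = N, fold_enrichment = fold, p_value = p)
}

#' Cluster-wise over-representation across gene-set collections
#'
#' Runs the hypergeometric test for every (cluster, collection, set)
#' combination against a common background (by default the expressed
#' genes), applying BH adjustment separately within each
#' (cluster, collection) analysis — one multiple-testing family per
#' enrichment run, as when each cluster is submitted to each collection
#' independently. Sets with no background members are dropped with a
#' warning.
#'
#' @param assignment `cluster_assignment`, or a named list of character
#'   vectors (cluster name -> genes).
#' @param collections A `gene_set_collection` or list of them.
#' @param background Character vector, the gene universe (e.g. all
#'   expressed genes); must cover every cluster.
#' @param fdr BH threshold for the `significant` flag.
#' @return data.frame of class `enrichment_table`: `cluster`, `collection`,
#'   `set_id`, `description`, `x`, `n`, `K`, `N`, `fold_enrichment`,
#'   `p_value`, `adjusted_p`, `significant`.
#' @export
enrich_all <- function(assignment, collections, background, fdr = 0.05) {
  clusters <- if (inherits(assignment, "cluster_assignment")) {
    split(names(assignment$cluster), assignment$cluster)
  } else {
    assignment
  }
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  if (length(collections) < 1L) stop("input error: need >= 1 collection")
  background <- unique(background)
  if (length(background) == 0L) stop("input error: empty background")
  if (any(vapply(clusters, length, integer(1)) > length(background))) {
    stop("input error: background smaller than a cluster")
  }

  rows <- list()
  for (coll in collections) {
    keep <- vapply(coll$sets, function(s) {
      length(intersect(s$genes, background)) > 0
    }, logical(1))
    if (any(!keep)) {
      warning("collection '", coll$name, "': dropped ", sum(!keep),
              " set(s) with no background members")
    }
    sets <- coll$sets[keep]
    if (length(sets) == 0L) next
    for (cl_name in names(clusters)) {
      res <- lapply(names(sets), function(sid) {
        h <- hypergeom_enrich(clusters[[cl_name]], sets[[sid]]$genes,
                              background)
        data.frame(cluster = cl_name, collection = coll$name, set_id = sid,
                   description = sets[[sid]]$description, x = h$x, n = h$n,
                   K = h$K, N = h$N, fold_enrichment = h$fold_enrichment,
                   p_value = h$p_value, stringsAsFactors = FALSE)
      })
      block <- do.call(rbind, res)
      block$adjusted_p <- bh_adjust(block$p_value)
      block$significant <- !is.na(block$adjusted_p) & block$adjusted_p < fdr
      rows[[length(rows) + 1L]] <- block
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(), collection = character(),
               set_id = character(), description = character(),
               x = integer(), n = integer(), K = integer(), N = integer(),
               fold_enrichment = numeric(), p_value = numeric(),
               adjusted_p = numeric(), significant = logical(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
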