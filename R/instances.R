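#' A set of protein-ligand instances with precomputed embeddings
#'
#' Each instance is a complex id paired with a variable-length residue-level
#' protein embedding matrix (n_residues x dProtein; e.g. 1152-dim residue
#' vectors from a protein language model) and a fixed-length pooled ligand
#' embedding vector (dLigand; e.g. 384-dim from a SMILES transformer).
#' Embedding extraction itself is out of scope: adapters supply the numbers.
#'
#' @slot ids character; unique instance (complex) ids.
#' @slot protein list of numeric matrices, one per instance, common column
#'   count dProtein.
#' @slot ligand numeric matrix (n x dLigand), one row per instance.
#' @slot benchmarkTag single character label.
#' @aliases InstanceSet-class
#' @exportClass InstanceSet
setClass("InstanceSet",
  representation(ids = "character", protein = "list", ligand = "matrix",
                 benchmarkTag = "character"))

setValidity("InstanceSet", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids)) return("instance ids must be unique")
  if (length(object@protein) != n || nrow(object@ligand) != n)
    return("ids, protein list and ligand matrix must agree in length")
  dP <- unique(vapply(object@protein, ncol, 1L))
  if (length(dP) > 1L) return("all protein matrices must share one dProtein")
  if (any(vapply(object@protein, nrow, 1L) < 1L))
    return("every protein needs at least one residue")
  finite <- all(vapply(object@protein, function(m) all(is.finite(m)), TRUE)) &&
    all(is.finite(object@ligand))
  if (!finite) return("embeddings must be finite")
  TRUE
})

#' @param ids,protein,ligand,benchmarkTag see slots.
#' @return an \code{InstanceSet}.
#' @rdname InstanceSet-class
#' @export
InstanceSet <- function(ids, protein, ligand, benchmarkTag = "unnamed") {
  rownames(ligand) <- ids
  names(protein) <- ids
  new("InstanceSet", ids = as.character(ids), protein = protein,
      ligand = ligand, benchmarkTag = benchmarkTag)
}

#' @rdname InstanceSet-class
#' @export
setMethod("proteinEmbeddings", "InstanceSet", function(x) x@protein)

#' @rdname InstanceSet-class
#' @export
setMethod("ligandEmbeddings", "InstanceSet", function(x) x@ligand)

#' @rdname InstanceSet-class
#' @export
setMethod("instanceIds", "InstanceSet", function(x) x@ids)

#' @rdname InstanceSet-class
#' @export
setMethod("embeddingDims", "InstanceSet", function(x)
  c(dProtein = ncol(x@protein[[1]]), dLigand = ncol(x@ligand)))

setMethod("show", "InstanceSet", function(object) {
  dims <- embeddingDims(object)
  lens <- vapply(object@protein, nrow, 1L)
  cat("InstanceSet '", object@benchmarkTag, "': ", length(object@ids),
      " instances | dProtein = ", dims[1], ", dLigand = ", dims[2],
      " | residues ", min(lens), "-", max(lens), "\n", sep = "")
})

#' Subset an InstanceSet by instance ids
#'
#' @param x an \code{InstanceSet}.
#' @param ids character vector of ids to keep (order preserved).
#' @return an \code{InstanceSet}.
#' @export
subsetInstances <- function(x, ids) {
  missing <- setdiff(ids, x@ids)
  if (length(missing))
    stop("unknown instance ids: ", paste(head(missing, 5), collapse = ", "))
  InstanceSet(ids, x@protein[ids], x@ligand[ids, , drop = FALSE],
              x@benchmarkTag)
}

#' Write / read the embedding store
#'
#' One container per benchmark, keyed by instance id; each key holds the
#' residue matrix (\code{protein}) and ligand vector (\code{ligand}).
#' Serialised as a single RDS container with that hierarchical layout.
#'
#' @param x an \code{InstanceSet}.
#' @param path store path (conventionally \code{embeddings.rds}).
#' @return \code{path} / an \code{InstanceSet}.
#' @export
writeEmbeddingStore <- function(x, path) {
  store <- lapply(seq_along(x@ids), function(i)
    list(protein = x@protein[[i]], ligand = as.numeric(x@ligand[i, ])))
  names(store) <- x@ids
  saveRDS(list(format = "dockselect-embedding-store", version = 1L,
               benchmarkTag = x@benchmarkTag, entries = store), path)
  invisible(path)
}

#' @rdname writeEmbeddingStore
#' @export
readEmbeddingStore <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dockselect-embedding-store"))
    stop(path, " is not an embedding store")
  ids <- names(obj$entries)
  protein <- lapply(obj$entries, `[[`, "protein")
  ligand <- do.call(rbind, lapply(obj$entries, `[[`, "ligand"))
  InstanceSet(ids, protein, ligand, obj$benchmarkTag)
}
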