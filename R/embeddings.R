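#' Word-embedding spaces
#'
#' An `embedding_space` holds a vocabulary of fixed-dimension real vectors,
#' the geometric substrate for every similarity score in the package. It is
#' stored as a numeric matrix with one row per (normalised) word, plus the
#' attributes `dims` (vector dimension) and `lowercase` (the case policy the
#' space was built with).
#'
#' @name embedding_space
NULL

new_embedding_space <- function(mat, lowercase = TRUE) {
  stopifnot(is.matrix(mat), is.numeric(mat), nrow(mat) >= 1L,
            !is.null(rownames(mat)))
  structure(mat,
            dims = ncol(mat),
            lowercase = lowercase,
            class = c("embedding_space", "matrix", "array"))
}

normalize_word <- function(word, lowercase = TRUE) {
  if (lowercase) tolower(word) else word
}

#' Load an embedding space from GloVe-style text
#'
#' Reads the de-facto text layout used by GloVe and word2vec releases:
#' one line per word, `word f1 f2 ... fD`, whitespace-separated, UTF-8,
#' no header. All-zero vectors are rejected because cosine similarity is
#' undefined for them.
#'
#' @param path Path to the embedding text file.
#' @param expected_dims If given, the file's dimension must equal it.
#' @param lowercase Lowercase vocabulary words on load (default `TRUE`,
#'   matching common embedding releases).
#' @return An `embedding_space`.
#' @export
load_embeddings <- function(path, expected_dims = NULL, lowercase = TRUE) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("embedding file is empty: ", path)

  parts <- strsplit(trimws(lines), "[ \t]+")
  words <- vapply(parts, `[[`, character(1), 1L)
  words <- normalize_word(words, lowercase)
  nfield <- lengths(parts)
  dims <- nfield[1L] - 1L
  if (dims < 1L) stop("format error at line 1: no vector components")
  bad <- which(nfield != nfield[1L])
  if (length(bad) > 0L)
    stop(sprintf("format error at line %d: expected %d components, found %d",
                 bad[1L], dims, nfield[bad[1L]] - 1L))
  if (!is.null(expected_dims) && dims != expected_dims)
    stop(sprintf("embedding dimension is %d, expected %d", dims, expected_dims))

  vecs <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1L]))
    v
  }, numeric(dims))
  vecs <- t(vecs)
  nonnum <- which(apply(vecs, 1L, function(v) any(is.na(v))))
  if (length(nonnum) > 0L)
    stop(sprintf("format error at line %d: non-numeric vector component",
                 nonnum[1L]))

  if (anyDuplicated(words)) {
    for (w in unique(words[duplicated(words)])) {
      idx <- which(words == w)
      ref <- vecs[idx[1L], ]
      for (i in idx[-1L])
        if (!isTRUE(all.equal(ref, vecs[i, ], tolerance = 0)))
          stop("duplicate word with conflicting vectors: ", w)
    }
    keep <- !duplicated(words)
    vecs <- vecs[keep, , drop = FALSE]
    words <- words[keep]
  }

  zero <- which(rowSums(vecs != 0) == 0L)
  if (length(zero) > 0L)
    stop("all-zero vector for word(s): ",
         paste(words[zero], collapse = ", "))

  rownames(vecs) <- words
  new_embedding_space(vecs, lowercase = lowercase)
}

#' Write an embedding space to GloVe-style text
#'
#' Inverse of [load_embeddings()]; vector components are serialised with
#' full precision (17 significant digits) so that a load/write round trip is
#' lossless.
#'
#' @param space An `embedding_space`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(space, path) {
  stopifnot(inherits(space, "embedding_space"))
  mat <- unclass(space)
  lines <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], formatC(mat[i, ], format = "g", digits = 17)),
          collapse = " ")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Look up a word vector
#'
#' Missingness is a value, not an error: a word absent from the vocabulary
#' yields `NULL`, never a silent zero vector.
#'
#' @param space An `embedding_space`.
#' @param word A single word string; normalised per the space's case policy.
#' @return The stored numeric vector, or `NULL` if the word is absent.
#' @export
embedding_vector <- function(space, word) {
  stopifnot(inherits(space, "embedding_space"), length(word) == 1L)
  w <- normalize_word(word, attr(space, "lowercase"))
  i <- match(w, rownames(space))
  if (is.na(i)) return(NULL)
  unclass(space)[i, ]
}

#' Test vocabulary membership
#'
#' @param space An `embedding_space`.
#' @param words Character vector of words (normalised per the case policy).
#' @return Logical vector.
#' @export
in_vocabulary <- function(space, words) {
  normalize_word(words, attr(space, "lowercase")) %in% rownames(space)
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (|u| |v|)`, the package's sole relatedness measure.
#'
#' @param u,v Numeric vectors of equal length, both non-zero.
#' @return A similarity score in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine is undefined for a zero-norm vector")
  sum(u * v) / (nu * nv)
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d words, %d dims, lowercase=%s>\n",
              nrow(x), attr(x, "dims"), attr(x, "lowercase")))
  invisible(x)
}

#' @export
dim.embedding_space <- function(x) dim(unclass(x))
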