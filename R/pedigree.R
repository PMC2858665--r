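#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' \code{fid} (family id), \code{iid} (individual id), \code{pat} and
#' \code{mat} (parent ids, \code{"0"} = unknown/founder) and \code{sex}
#' (optional code, \code{0} = unknown). Individual ids must be unique across
#' the whole pedigree; each non-zero parent reference must resolve to a row,
#' and the parent graph must be acyclic.
#'
#' @param fid,iid,pat,mat,sex character/numeric vectors of equal length.
#' @return An object of class \code{fammdr_ped} (a data frame).
#' @examples
#' ped <- pedigree(fid = "1", iid = c("p1", "p2", "c1"),
#'                 pat = c("0", "0", "p1"), mat = c("0", "0", "p2"))
#' @export
pedigree <- function(fid, iid, pat, mat, sex = NULL) {
  iid <- as.character(iid)
  ped <- data.frame(fid = as.character(fid), iid = iid,
                    pat = as.character(pat), mat = as.character(mat),
                    sex = if (is.null(sex)) 0L else as.integer(sex),
                    stringsAsFactors = FALSE)
  ped$pat[is.na(ped$pat)] <- "0"
  ped$mat[is.na(ped$mat)] <- "0"
  validate_pedigree(ped)
  class(ped) <- c("fammdr_ped", "data.frame")
  ped
}

#' @rdname pedigree
#' @param ped a pedigree data frame.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(all(c("fid", "iid", "pat", "mat") %in% names(ped)))
  if (anyDuplicated(ped$iid))
    stop("duplicated individual ids: ",
         paste(unique(ped$iid[duplicated(ped$iid)]), collapse = ", "))
  known <- c("0", ped$iid)
  bad <- setdiff(c(ped$pat, ped$mat), known)
  if (length(bad))
    stop("parent ids not found in pedigree: ", paste(bad, collapse = ", "))
  pedigree_order(ped)  # errors on cycles
  invisible(ped)
}

# Topological order: founders first, every parent before its children.
# Kahn's algorithm; a leftover individual implies a cycle.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$iid
  fa <- unname(idx[ped$pat]); fa[is.na(fa)] <- 0L
  mo <- unname(idx[ped$mat]); mo[is.na(mo)] <- 0L
  indeg <- (fa > 0L) + (mo > 0L)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (fa[i] > 0L) children[[fa[i]]] <- c(children[[fa[i]]], i)
    if (mo[i] > 0L) children[[mo[i]]] <- c(children[[mo[i]]], i)
  }
  queue <- integer(n)
  tail <- 0L
  for (i in which(indeg == 0L)) { tail <- tail + 1L; queue[tail] <- i }
  head <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) { tail <- tail + 1L; queue[tail] <- ch }
    }
  }
  if (tail < n)
    stop("pedigree contains a cycle (individual is its own ancestor)")
  queue
}

#' Additive relationship matrix from a pedigree
#'
#' Computes the additive genetic relationship matrix A (twice the kinship
#' matrix) by the standard recursive tabular method: founders are unrelated
#' and non-inbred, \eqn{A_{ii} = 1 + A_{f(i),m(i)}/2} and
#' \eqn{A_{ij} = (A_{j,f(i)} + A_{j,m(i)})/2} for j not a descendant of i.
#' Unknown parents are treated as unique unrelated founders. Individuals kept
#' in the pedigree only to connect relatives contribute to the computation;
#' use \code{ids} to subset the returned matrix to the analyzed individuals.
#'
#' @param ped a \code{fammdr_ped} or compatible data frame.
#' @param ids ordered character vector of individual ids for the returned
#'   matrix (default: all individuals in pedigree order).
#' @return A symmetric numeric matrix with \code{ids} as dimnames; diagonal
#'   \eqn{1 + F_i} with F the inbreeding coefficient.
#' @examples
#' ped <- pedigree(fid = "1", iid = c("p1", "p2", "c1", "c2"),
#'                 pat = c("0", "0", "p1", "p1"), mat = c("0", "0", "p2", "p2"))
#' additive_relationship(ped)["c1", "c2"]  # full sibs: 0.5
#' @export
additive_relationship <- function(ped, ids = NULL) {
  validate_pedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$iid
  if (is.null(ids)) ids <- ped$iid
  miss <- setdiff(ids, ped$iid)
  if (length(miss))
    stop("ids not found in pedigree: ", paste(miss, collapse = ", "))
  fa <- unname(idx[ped$pat]); fa[is.na(fa)] <- 0L
  mo <- unname(idx[ped$mat]); mo[is.na(mo)] <- 0L
  ord <- pedigree_order(ped)
  A <- matrix(0, n, n, dimnames = list(ped$iid, ped$iid))
  for (k in seq_along(ord)) {
    i <- ord[k]
    f <- fa[i]; m <- mo[i]
    if (k > 1L) {
      prev <- ord[seq_len(k - 1L)]
      av <- 0.5 * ((if (f > 0L) A[prev, f] else 0) +
                   (if (m > 0L) A[prev, m] else 0))
      A[prev, i] <- av
      A[i, prev] <- av
    }
    A[i, i] <- 1 + (if (f > 0L && m > 0L) 0.5 * A[f, m] else 0)
  }
  A[ids, ids, drop = FALSE]
}

#' Read / write PLINK FAM pedigree files
#'
#' The FAM dialect is whitespace-delimited with six columns
#' FID IID PAT MAT SEX PHENO and no header; \code{"0"} marks an unknown
#' parent.
#'
#' @param path file path.
#' @return \code{read_fam}: a \code{fammdr_ped} with an extra \code{pheno}
#'   column (as read, \code{-9}/\code{0} conventionally missing).
#' @export
read_fam <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(raw) < 4L) stop("FAM file needs at least FID IID PAT MAT columns")
  if (ncol(raw) < 6L) raw <- cbind(raw, matrix("0", nrow(raw), 6L - ncol(raw)))
  ped <- pedigree(fid = raw[[1L]], iid = raw[[2L]], pat = raw[[3L]],
                  mat = raw[[4L]], sex = suppressWarnings(as.integer(raw[[5L]])))
  ped$pheno <- suppressWarnings(as.numeric(raw[[6L]]))
  ped
}

#' @rdname read_fam
#' @param ped pedigree to write.
#' @export
write_fam <- function(ped, path) {
  pheno <- if ("pheno" %in% names(ped)) ped$pheno else -9
  out <- data.frame(ped$fid, ped$iid, ped$pat, ped$mat,
                    if ("sex" %in% names(ped)) ped$sex else 0L, pheno)
  utils::write.table(out, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a relationship matrix as TSV
#'
#' Square matrix with a header row of ids and one labeled row per id.
#'
#' @param A matrix with dimnames; \code{path} file path.
#' @export
write_relationship_tsv <- function(A, path) {
  df <- data.frame(iid = rownames(A), A, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relationship_tsv
#' @export
read_relationship_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = c(iid = "character"))
  A <- as.matrix(df[, -1L, drop = FALSE])
  rownames(A) <- df$iid
  storage.mode(A) <- "double"
  A
}
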