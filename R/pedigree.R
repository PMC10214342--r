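#' Read and validate a pedigree from CSV
#'
#' Reads a pedigree table with columns \code{individual}, \code{dam},
#' \code{sire}, \code{group} (and optionally \code{sex}), validates it, and
#' returns a \code{pedigree} object with parents ordered before offspring.
#' Unknown parents may be encoded as empty strings, \code{NA}, \code{"NA"},
#' \code{"0"} or \code{"*"}. A dam or sire named in the table but never
#' listed as an individual is promoted to a founder (both parents unknown)
#' with its offspring's group.
#'
#' @param path Path to a CSV file.
#' @param unknown Character vector of tokens interpreted as "parent unknown".
#' @return An object of class \code{pedigree}: a list with elements
#'   \code{records} (data frame with columns individual, dam, sire, group,
#'   sex, in topological order) and \code{founders_promoted} (character
#'   vector of auto-added founders).
#' @seealso [as_pedigree()], [additive_relationship_matrix()]
#' @export
read_pedigree <- function(path, unknown = c("", "NA", "0", "*")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_pedigree(df, unknown = unknown)
}

#' Build a validated pedigree from a data frame
#'
#' @param df Data frame with columns individual, dam, sire and optionally
#'   group and sex.
#' @inheritParams read_pedigree
#' @return A \code{pedigree} object; see [read_pedigree()].
#' @export
as_pedigree <- function(df, unknown = c("", "NA", "0", "*")) {
  need <- c("individual", "dam", "sire")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("pedigree table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"group" %in% names(df)) df$group <- NA_character_
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df <- df[, c("individual", "dam", "sire", "group", "sex")]
  for (col in names(df)) df[[col]] <- as.character(df[[col]])
  df$dam[df$dam %in% unknown | is.na(df$dam)] <- NA_character_
  df$sire[df$sire %in% unknown | is.na(df$sire)] <- NA_character_

  if (anyNA(df$individual) || any(df$individual %in% unknown))
    stop("missing or sentinel individual id in pedigree")
  dup <- df$individual[duplicated(df$individual)]
  if (length(dup) > 0L)
    stop("duplicate individual id(s) in pedigree: ",
         paste(unique(dup), collapse = ", "))
  own <- df$individual == df$dam | df$individual == df$sire
  own[is.na(own)] <- FALSE
  if (any(own))
    stop("individual listed as its own parent: ",
         paste(df$individual[own], collapse = ", "))

  ## promote parents never listed as individuals to founders
  parents <- unique(stats::na.omit(c(df$dam, df$sire)))
  promote <- setdiff(parents, df$individual)
  if (length(promote) > 0L) {
    grp <- vapply(promote, function(p) {
      g <- df$group[df$dam %in% p | df$sire %in% p]
      g <- g[!is.na(g)]
      if (length(g) > 0L) g[1L] else NA_character_
    }, character(1L))
    sex <- ifelse(promote %in% df$dam, "female",
                  ifelse(promote %in% df$sire, "male", "unknown"))
    df <- rbind(df, data.frame(individual = promote, dam = NA_character_,
                               sire = NA_character_, group = grp, sex = sex,
                               stringsAsFactors = FALSE))
  }

  ord <- pedigree_toposort(df)
  df <- df[match(ord, df$individual), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(records = df, founders_promoted = promote),
            class = "pedigree")
}

## Kahn's algorithm over parent -> offspring edges; on failure, names one
## individual involved in a cycle.
pedigree_toposort <- function(df) {
  ids <- df$individual
  idx <- seq_along(ids)
  names(idx) <- ids
  n_parents <- (!is.na(df$dam)) + (!is.na(df$sire))
  children <- vector("list", length(ids))
  for (i in idx) {
    for (p in c(df$dam[i], df$sire[i])) {
      if (!is.na(p)) {
        j <- idx[[p]]
        children[[j]] <- c(children[[j]], i)
      }
    }
  }
  queue <- which(n_parents == 0L)
  out <- integer(0)
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    out <- c(out, i)
    for (j in children[[i]]) {
      n_parents[j] <- n_parents[j] - 1L
      if (n_parents[j] == 0L) queue <- c(queue, j)
    }
  }
  if (length(out) < length(ids)) {
    bad <- ids[setdiff(idx, out)]
    stop("pedigree contains a parent-offspring cycle involving: ",
         paste(bad, collapse = ", "))
  }
  ids[out]
}

#' @export
print.pedigree <- function(x, ...) {
  r <- x$records
  cat("Pedigree:", nrow(r), "individuals,",
      sum(is.na(r$dam) & is.na(r$sire)), "founders,",
      length(unique(stats::na.omit(r$group))), "group(s)\n")
  if (length(x$founders_promoted) > 0L)
    cat("  auto-promoted founders:",
        paste(x$founders_promoted, collapse = ", "), "\n")
  invisible(x)
}

#' Additive genetic relationship matrix
#'
#' Computes the additive relationship matrix A from a pedigree by the
#' Henderson tabular method, processing individuals in topological order:
#' \deqn{A_{ii} = 1 + 0.5 A_{d(i), s(i)}, \quad
#'       A_{ij} = 0.5 (A_{j, d(i)} + A_{j, s(i)})}
#' where \eqn{d(i)}, \eqn{s(i)} are the dam and sire of \eqn{i} and an
#' unknown parent contributes 0. Entries are twice the kinship coefficient;
#' the diagonal is one plus the inbreeding coefficient. Founders are assumed
#' unrelated and non-inbred.
#'
#' @param ped A \code{pedigree} object.
#' @return A symmetric numeric matrix with the pedigree's individuals as
#'   dimnames, in topological order.
#' @export
additive_relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  r <- ped$records
  n <- nrow(r)
  idx <- seq_len(n)
  names(idx) <- r$individual
  dam <- ifelse(is.na(r$dam), 0L, idx[r$dam])
  sire <- ifelse(is.na(r$sire), 0L, idx[r$sire])
  A <- matrix(0, n, n, dimnames = list(r$individual, r$individual))
  for (i in idx) {
    d <- dam[i]; s <- sire[i]
    A[i, i] <- 1 + if (d > 0L && s > 0L) 0.5 * A[d, s] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (d > 0L) A[j, d] else 0) +
                    (if (s > 0L) A[j, s] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  A
}

#' Recursive kinship oracle
#'
#' Computes the additive relatedness of a pair of individuals directly from
#' the recursive definition of the kinship coefficient, without the tabular
#' shortcut: \eqn{2\phi(i,j)} for \eqn{i \neq j} and \eqn{1 + F_i =
#' 2\phi(i,i)} on the diagonal. Exponential-time recursion; intended as an
#' independent cross-check of [additive_relationship_matrix()] on small
#' pedigrees.
#'
#' @param ped A \code{pedigree} object (of modest size).
#' @param i,j Individual identifiers.
#' @return A single relatedness value.
#' @export
kinship_oracle <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  r <- ped$records
  pos <- seq_len(nrow(r))
  names(pos) <- r$individual
  if (!i %in% r$individual) stop("unknown individual: ", i)
  if (!j %in% r$individual) stop("unknown individual: ", j)
  dam <- r$dam; sire <- r$sire
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    ia <- pos[[a]]; ib <- pos[[b]]
    if (ia == ib) {
      return(0.5 * (1 + phi(dam[ia], sire[ia])))
    }
    ## recurse on the individual appearing later in topological order,
    ## whose parents are guaranteed earlier
    if (ia < ib) { tmp <- a; a <- b; b <- tmp; ib <- pos[[a]] }
    ia <- pos[[a]]
    0.5 * (phi(dam[ia], b) + phi(sire[ia], b))
  }
  2 * phi(i, j)
}

#' Map sample-table identifiers to A-matrix rows
#'
#' The A matrix follows the pedigree's topological order, which in general
#' differs from the order individuals appear in a sample table. This helper
#' returns, for a vector of identifiers, their row/column positions in A.
#'
#' @param A A relatedness matrix with id dimnames.
#' @param ids Character vector of identifiers.
#' @return Integer vector of positions in \code{A}.
#' @export
relatedness_index <- function(A, ids) {
  pos <- match(ids, rownames(A))
  if (anyNA(pos))
    stop("identifiers absent from relatedness matrix: ",
         paste(unique(ids[is.na(pos)]), collapse = ", "))
  pos
}

#' Add missing individuals to a pedigree as founders
#'
#' Individuals present in a sample table but absent from the pedigree are
#' appended as founders (both parents unknown) with a warning, so that the
#' animal model can still index every sampled individual in A.
#'
#' @param ped A \code{pedigree} object.
#' @param ids Identifiers that must be present.
#' @param groups Optional character vector of the same length giving each
#'   id's group.
#' @return A \code{pedigree} containing all of \code{ids}.
#' @export
ensure_in_pedigree <- function(ped, ids, groups = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  ids <- as.character(ids)
  missing_ids <- setdiff(unique(ids), ped$records$individual)
  if (length(missing_ids) == 0L) return(ped)
  warning(length(missing_ids),
          " sampled individual(s) absent from pedigree; added as founders: ",
          paste(missing_ids, collapse = ", "))
  grp <- rep(NA_character_, length(missing_ids))
  if (!is.null(groups)) {
    m <- match(missing_ids, ids)
    grp <- as.character(groups)[m]
  }
  df <- rbind(ped$records,
              data.frame(individual = missing_ids, dam = NA_character_,
                         sire = NA_character_, group = grp,
                         sex = NA_character_, stringsAsFactors = FALSE))
  out <- as_pedigree(df)
  out$founders_promoted <- union(ped$founders_promoted, missing_ids)
  out
}

#' Write a relatedness matrix as CSV
#'
#' Dense CSV with an id header row and a leading id column.
#'
#' @param A Relatedness matrix with dimnames.
#' @param path Output path.
#' @export
write_relatedness <- function(A, path) {
  df <- data.frame(id = rownames(A), A, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a relatedness matrix written by [write_relatedness()]
#'
#' @param path CSV path.
#' @return A symmetric numeric matrix with id dimnames.
#' @export
read_relatedness <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(id = "character"))
  A <- as.matrix(df[, -1, drop = FALSE])
  rownames(A) <- df$id
  storage.mode(A) <- "double"
  A
}
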