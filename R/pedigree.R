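#' Topologically sort a pedigree
#'
#' Orders individuals so that every parent precedes its offspring, detecting
#' cycles (an individual that is its own ancestor). Unknown parents are `NA`.
#'
#' @param pedigree Tibble with `id`, `dam`, `sire` columns; extra columns are
#'   carried along.
#' @return The pedigree tibble reordered parents-before-offspring.
#' @export
sort_pedigree <- function(pedigree) {
  pedigree <- tibble::as_tibble(pedigree)
  id <- as.character(pedigree$id)
  if (anyDuplicated(id) > 0) stop("duplicated individual ids", call. = FALSE)
  dam <- match(as.character(pedigree$dam), id)
  sire <- match(as.character(pedigree$sire), id)
  n <- length(id)
  depth_in <- integer(n)  # number of unplaced parents
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(dam[i], sire[i])) {
      if (!is.na(p)) {
        depth_in[i] <- depth_in[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order <- integer(0)
  queue <- which(depth_in == 0L)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    order <- c(order, i)
    for (ch in children[[i]]) {
      depth_in[ch] <- depth_in[ch] - 1L
      if (depth_in[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) < n) {
    cyc <- id[setdiff(seq_len(n), order)]
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(cyc, 5), collapse = ", "), call. = FALSE)
  }
  pedigree[order, , drop = FALSE]
}

#' Additive relationship matrix (tabular method)
#'
#' Computes Wright's numerator relationship matrix A by the tabular method:
#' `A[i,i] = 1 + F_i` with `F_i = A[dam_i, sire_i] / 2`, and
#' `A[i,j] = (A[j, dam_i] + A[j, sire_i]) / 2` for `j` preceding `i`. Unknown
#' parents contribute zero relationship, i.e. they are treated as unique
#' unrelated founders.
#'
#' @param pedigree Tibble with `id`, `dam`, `sire`.
#' @return Dense symmetric matrix with dimnames = individual ids, in
#'   topological order.
#' @export
additive_relationship <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  id <- as.character(ped$id)
  dam <- match(as.character(ped$dam), id)
  sire <- match(as.character(ped$sire), id)
  n <- length(id)
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (!is.na(d)) rel <- rel + A[j, d]
      if (!is.na(s)) rel <- rel + A[j, s]
      rel <- rel / 2
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (!is.na(d) && !is.na(s)) A[d, s] / 2 else 0
  }
  A
}

#' Inbreeding coefficients with the unknown-grandparent rule
#'
#' F is taken from the diagonal of the additive relationship matrix
#' (`A[i,i] - 1`), but is reported as missing whenever any parent *or*
#' grandparent of the individual is unknown: with incomplete ancestry the
#' pedigree-based F systematically understates inbreeding, so such values are
#' treated as unknown rather than zero.
#'
#' @param pedigree Tibble with `id`, `dam`, `sire`.
#' @return Tibble with `id`, `F` (NA when ancestry is incomplete) and
#'   `F_raw` (the tabular value regardless of completeness).
#' @export
inbreeding_coefficients <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  A <- additive_relationship(ped)
  id <- as.character(ped$id)
  dam <- as.character(ped$dam)
  sire <- as.character(ped$sire)
  parents_of <- stats::setNames(Map(c, dam, sire), id)
  complete <- vapply(seq_along(id), function(i) {
    p <- c(dam[i], sire[i])
    if (anyNA(p)) return(FALSE)
    gp <- unlist(parents_of[p], use.names = FALSE)
    length(gp) == 4 && !anyNA(gp)
  }, logical(1))
  F_raw <- diag(A) - 1
  tibble::tibble(
    id = id,
    F = ifelse(complete, F_raw, NA_real_),
    F_raw = F_raw
  )
}

#' Per-individual generation depth
#'
#' Depth of an individual is the length of the longest chain of known
#' ancestors ending at it; founders have depth 0 under the default
#' convention. Since "generation depth" conventions vary (some count founders
#' as generation 1), the summary reports the mean under both.
#'
#' @param pedigree Tibble with `id`, `dam`, `sire`.
#' @return List with `depths` (tibble id, depth) and `summary` (max, mean
#'   with founders = 0, mean with founders = 1).
#' @export
pedigree_depth <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  id <- as.character(ped$id)
  dam <- match(as.character(ped$dam), id)
  sire <- match(as.character(ped$sire), id)
  n <- length(id)
  depth <- integer(n)
  for (i in seq_len(n)) {
    d <- 0L
    if (!is.na(dam[i])) d <- max(d, depth[dam[i]] + 1L)
    if (!is.na(sire[i])) d <- max(d, depth[sire[i]] + 1L)
    depth[i] <- d
  }
  list(
    depths = tibble::tibble(id = id, depth = depth),
    summary = tibble::tibble(
      max_depth = max(depth),
      mean_depth_founder0 = mean(depth),
      mean_depth_founder1 = mean(depth + 1L)
    )
  )
}

#' Simulate breeding values down a pedigree
#'
#' Founders draw breeding values from Normal(0, sigma2_A); a non-founder gets
#' the mid-parent mean plus a Mendelian-segregation deviation with variance
#' `sigma2_A * (1/2 - (F_dam + F_sire)/4)`. An unknown parent's contribution
#' is drawn as an independent founder share, i.e. half the parental average is
#' replaced by a draw from Normal(0, sigma2_A / 4) folded into the deviation
#' term (variance `sigma2_A * 3/4` with one unknown parent, `sigma2_A` with
#' two).
#'
#' @param pedigree Tibble with `id`, `dam`, `sire`.
#' @param sigma2_A Additive genetic variance (>= 0).
#' @param seed Optional integer seed.
#' @return Tibble with `id` and `bv`, in topological order.
#' @export
simulate_breeding_values <- function(pedigree, sigma2_A, seed = NULL) {
  stopifnot(sigma2_A >= 0)
  if (!is.null(seed)) set.seed(seed)
  ped <- sort_pedigree(pedigree)
  id <- as.character(ped$id)
  dam <- match(as.character(ped$dam), id)
  sire <- match(as.character(ped$sire), id)
  n <- length(id)
  if (sigma2_A == 0) return(tibble::tibble(id = id, bv = rep(0, n)))
  Fcoef <- diag(additive_relationship(ped)) - 1
  bv <- numeric(n)
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    if (is.na(d) && is.na(s)) {
      bv[i] <- rnorm(1, 0, sqrt(sigma2_A))
    } else {
      mid <- 0
      v_mend <- 0
      for (p in list(d, s)) {
        if (is.na(p)) {
          # unknown parent: its half-share behaves like a founder gamete
          v_mend <- v_mend + sigma2_A / 4 + sigma2_A / 4  # transmission + segregation
        } else {
          mid <- mid + bv[p] / 2
          v_mend <- v_mend + sigma2_A * (1 - Fcoef[p]) / 4
        }
      }
      bv[i] <- mid + rnorm(1, 0, sqrt(v_mend))
    }
  }
  tibble::tibble(id = id, bv = bv)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A^-1 directly from the pedigree using Henderson's rules with the
#' inbreeding adjustment: each individual contributes to the inverse through
#' its Mendelian-sampling variance
#' `d_i = 1 - 0.25 * (1 + F_dam) - 0.25 * (1 + F_sire)` terms (a missing
#' parent drops its term). Used by the animal-model sampler.
#'
#' @param pedigree Tibble with `id`, `dam`, `sire`.
#' @return Sparse symmetric `Matrix::dsCMatrix` with dimnames = ids in
#'   topological order.
#' @export
additive_relationship_inverse <- function(pedigree) {
  ped <- sort_pedigree(pedigree)
  id <- as.character(ped$id)
  dam <- match(as.character(ped$dam), id)
  sire <- match(as.character(ped$sire), id)
  n <- length(id)
  Fcoef <- diag(additive_relationship(ped)) - 1
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    d <- dam[i]; s <- sire[i]
    v_ms <- 1
    if (!is.na(d)) v_ms <- v_ms - 0.25 * (1 + Fcoef[d])
    if (!is.na(s)) v_ms <- v_ms - 0.25 * (1 + Fcoef[s])
    w <- 1 / v_ms
    push(i, i, w)
    for (p in c(d, s)) {
      if (!is.na(p)) {
        push(i, p, -w / 2); push(p, i, -w / 2)
        push(p, p, w / 4)
      }
    }
    if (!is.na(d) && !is.na(s)) {
      push(d, s, w / 4); push(s, d, w / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(id, id))
  methods::as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Drops individuals that neither carry phenotypes nor connect phenotyped
#' individuals through ancestry; relationships among the kept individuals are
#' unchanged. Standard practice before fitting an animal model, purely to
#' reduce the size of the mixed-model equations.
#'
#' @param pedigree Tibble with `id`, `dam`, `sire`.
#' @param keep Character vector of ids that must be retained.
#' @return Pruned pedigree tibble in topological order.
#' @export
prune_pedigree <- function(pedigree, keep) {
  ped <- sort_pedigree(pedigree)
  id <- as.character(ped$id)
  dam <- as.character(ped$dam)
  sire <- as.character(ped$sire)
  needed <- id %in% as.character(keep)
  # sweep from youngest to oldest, marking ancestors of needed individuals
  for (i in rev(seq_along(id))) {
    if (needed[i]) {
      for (p in c(dam[i], sire[i])) {
        if (!is.na(p)) needed[match(p, id)] <- TRUE
      }
    }
  }
  ped[needed, , drop = FALSE]
}

#' Write an additive relationship matrix as sparse triplets
#'
#' Plain-text `i`, `j`, `value` triplets (upper triangle including diagonal),
#' tab-separated, with ids resolved to names.
#'
#' @param A Matrix from [additive_relationship()].
#' @param path Output path.
#' @param tol Entries with |value| <= tol are omitted.
#' @export
write_relationship_triplets <- function(A, path, tol = 0) {
  idx <- which(upper.tri(A, diag = TRUE) & abs(A) > tol, arr.ind = TRUE)
  df <- tibble::tibble(
    i = rownames(A)[idx[, 1]],
    j = colnames(A)[idx[, 2]],
    value = A[idx]
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
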