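#' Pedigree container
#'
#' Builds a validated pedigree from individual/sire/dam records. Parents must
#' either be present in the pedigree or be marked unknown with the sentinel
#' `0` (or `NA`). Rows are re-ordered topologically so that parents always
#' precede offspring; a cycle (an individual that is its own ancestor) or a
#' reference to an id that is neither listed nor unknown is a structural error.
#'
#' @param id vector of individual ids (coerced to character).
#' @param sire,dam parent ids; `0` or `NA` for unknown.
#' @param generation optional integer generation index (informational).
#' @param sex optional sex code (informational; `"F"`/`"M"` in generated data).
#' @return An object of class `pedigree`: a data.frame with columns
#'   `id`, `sire`, `dam`, `generation`, `sex`, topologically ordered, plus
#'   integer parent indices in attributes used by downstream code.
#' @export
pedigree <- function(id, sire, dam, generation = NA_integer_, sex = NA_character_) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[is.na(sire) | sire == "0"] <- NA_character_
  dam[is.na(dam) | dam == "0"] <- NA_character_
  if (anyDuplicated(id)) {
    stop("structural pedigree error: duplicated individual ids: ",
         paste(utils::head(id[duplicated(id)], 5L), collapse = ", "))
  }
  known <- c(sire[!is.na(sire)], dam[!is.na(dam)])
  missing_ref <- setdiff(known, id)
  if (length(missing_ref)) {
    stop("structural pedigree error: parent id(s) not in pedigree: ",
         paste(utils::head(missing_ref, 5L), collapse = ", "))
  }
  df <- data.frame(id = id, sire = sire, dam = dam,
                   generation = rep_len(as.integer(generation), length(id)),
                   sex = rep_len(as.character(sex), length(id)),
                   stringsAsFactors = FALSE)

  ## Kahn topological sort: parents before offspring; detects cycles.
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  si <- ifelse(is.na(df$sire), 0L, idx[df$sire])
  di <- ifelse(is.na(df$dam), 0L, idx[df$dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order_out <- c(order_out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order_out) != n) {
    stop("structural pedigree error: pedigree contains a cycle")
  }
  df <- df[order_out, , drop = FALSE]
  rownames(df) <- NULL
  idx <- stats::setNames(seq_len(n), df$id)
  attr(df, "sire_idx") <- unname(ifelse(is.na(df$sire), 0L, idx[df$sire]))
  attr(df, "dam_idx")  <- unname(ifelse(is.na(df$dam), 0L, idx[df$dam]))
  class(df) <- c("pedigree", "data.frame")
  df
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d individuals, %d founders\n",
              nrow(x), sum(is.na(x$sire) & is.na(x$dam))))
  invisible(x)
}

#' Read / write a pedigree CSV
#'
#' CSV dialect: header `id,sire,dam,generation,sex`, sentinel `0` for an
#' unknown parent. Rows need not be sorted; ordering is repaired on load.
#'
#' @param path file path.
#' @return `read_pedigree`: a [pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) {
    stop("pedigree CSV must have columns id,sire,dam (optionally generation,sex)")
  }
  pedigree(df$id, df$sire, df$dam,
           generation = if ("generation" %in% names(df)) as.integer(df$generation) else NA_integer_,
           sex = if ("sex" %in% names(df)) df$sex else NA_character_)
}

#' @param ped a [pedigree()] object.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inbreeding coefficients and Mendelian-sampling variances
#'
#' Meuwissen & Luo style pass over the ordered pedigree. Founders are assumed
#' unrelated and non-inbred. The Mendelian-sampling variance `d` returned for
#' each individual is the within-family variance used by Henderson's rules:
#' `0.5 - 0.25 (F_s + F_d)` with both parents known, `0.75 - 0.25 F_p` with one
#' parent known, and `1` for a founder.
#'
#' @param ped a [pedigree()] object.
#' @param ids optional subset of ids for which the inbreeding coefficient is
#'   required (others are returned as `NA`); the Mendelian-sampling variance
#'   `d` is always returned for everyone. Tracing F for an individual only
#'   needs F of its ancestors-that-are-parents, so restricting `ids` to the
#'   individuals that actually appear as parents (what [build_A_inverse()]
#'   does) skips most of the work on large final cohorts.
#' @return list with numeric vectors `F` (inbreeding) and `d`
#'   (Mendelian-sampling variance), in pedigree order.
#' @export
inbreeding <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  is_parent <- logical(n)
  is_parent[si[si > 0L]] <- TRUE
  is_parent[di[di > 0L]] <- TRUE
  if (is.null(ids)) {
    need <- rep(TRUE, n)
  } else {
    need <- ped$id %in% as.character(ids) | is_parent
  }
  ## F of any ancestor that is itself a parent must be available before it is
  ## needed in a descendant's Mendelian-sampling variance.
  need <- need | is_parent
  Fc <- rep(NA_real_, n)
  Lv <- numeric(n)  # reusable ancestor-contribution workspace
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (s == 0L || d == 0L) {
      Fc[i] <- 0  # founder or single known parent: unrelated-founder assumption
    } else if (need[i]) {
      ## a_ii = sum over ancestors j (incl. i) of L_j^2 d_j, descending order
      Lv[i] <- 1
      work <- i
      aii <- 0
      while (length(work)) {
        j <- max(work)
        work <- work[work != j]
        lj <- Lv[j]
        Lv[j] <- 0
        sj <- si[j]; dj <- di[j]
        if (sj > 0L) {
          if (Lv[sj] == 0) work <- c(work, sj)
          Lv[sj] <- Lv[sj] + lj / 2
        }
        if (dj > 0L) {
          if (Lv[dj] == 0) work <- c(work, dj)
          Lv[dj] <- Lv[dj] + lj / 2
        }
        aii <- aii + lj^2 * dv0(sj, dj, Fc)
      }
      Fc[i] <- aii - 1
    }
  }
  dv <- vapply(seq_len(n), function(i) dv0(si[i], di[i], Fc), numeric(1))
  list(F = Fc, d = dv)
}

## Mendelian-sampling variance given parent indices and inbreeding vector.
dv0 <- function(s, d, Fc) {
  if (s == 0L && d == 0L) return(1)
  if (s == 0L || d == 0L) return(0.75 - 0.25 * Fc[max(s, d)])
  0.5 - 0.25 * (Fc[s] + Fc[d])
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense recursive (tabular) construction of the additive relationship matrix
#' A over all pedigree members, including inbreeding on the diagonal
#' (`a_ii = 1 + F_i`). Quadratic in pedigree size; intended for pedigrees up to
#' a few thousand ids. Mixed-model code never forms A; it uses
#' [build_A_inverse()].
#'
#' @param ped a [pedigree()] object.
#' @return symmetric `Matrix::dsyMatrix` with ids as dimnames.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    asd <- if (s > 0L && d > 0L) A[s, d] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else numeric(i - 1L)
      ad_ <- if (d > 0L) A[j, d] else numeric(i - 1L)
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  methods::as(Matrix::Matrix(A, sparse = FALSE), "symmetricMatrix")
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with exact inbreeding: each individual contributes
#' `1/d_i` to its own diagonal, `-1/(2 d_i)` to individual-parent cells and
#' `1/(4 d_i)` to parent-parent cells, with `d_i` from [inbreeding()].
#'
#' @param ped a [pedigree()] object.
#' @return sparse symmetric `Matrix::dsCMatrix` with ids as dimnames;
#'   `build_A_inverse(ped) %*% build_A(ped)` is the identity.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  dv <- inbreeding(ped, ids = character(0))$d  # F needed for parents only
  ## accumulate triplets in one pass (vectorized over individuals)
  alpha <- 1 / dv
  i_all <- seq_len(n)
  ii <- i_all; jj <- i_all; xx <- alpha
  for (pcol in list(si, di)) {
    has <- pcol > 0L
    ii <- c(ii, i_all[has], pcol[has])
    jj <- c(jj, pcol[has], i_all[has])
    xx <- c(xx, rep(-alpha[has] / 2, 2L))
  }
  both <- si > 0L & di > 0L
  one_s <- si > 0L
  one_d <- di > 0L
  ## parent-parent quarter terms: s-s, d-d, s-d, d-s
  ii <- c(ii, si[one_s], di[one_d], si[both], di[both])
  jj <- c(jj, si[one_s], di[one_d], di[both], si[both])
  xx <- c(xx, alpha[one_s] / 4, alpha[one_d] / 4, alpha[both] / 4, alpha[both] / 4)
  Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                             dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ai)
}
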