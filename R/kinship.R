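#' Construct a pedigree object
#'
#' A pedigree is a set of records (family, individual, father, mother, sex)
#' in the conventional ped-file encoding: `"0"` marks a missing parent, sex is
#' 1 = male, 2 = female. Founders have both parents missing. Individuals with
#' exactly one known parent are completed with a synthetic unknown founder so
#' that the kinship recursion stays total.
#'
#' @param family_id,individual_id,father_id,mother_id character vectors of
#'   equal length; parent ids use `"0"` for missing.
#' @param sex integer vector, 1 = male, 2 = female.
#' @return An object of class `pedigree`: a data.frame with columns
#'   `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`.
#' @export
pedigree <- function(family_id, individual_id, father_id, mother_id, sex) {
  ped <- data.frame(
    family_id = as.character(family_id),
    individual_id = as.character(individual_id),
    father_id = as.character(father_id),
    mother_id = as.character(mother_id),
    sex = as.integer(sex),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ped$individual_id))
    stop("duplicate individual ids: ",
         paste(unique(ped$individual_id[duplicated(ped$individual_id)]),
               collapse = ", "))
  ped <- complete_single_parents(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# one known parent -> add a synthetic unknown founder as the other parent
complete_single_parents <- function(ped) {
  one <- xor(ped$father_id == "0", ped$mother_id == "0")
  if (!any(one)) return(ped)
  for (i in which(one)) {
    new_id <- paste0("UNK_", ped$individual_id[i])
    if (ped$father_id[i] == "0") {
      ped$father_id[i] <- new_id
      new_sex <- 1L
    } else {
      ped$mother_id[i] <- new_id
      new_sex <- 2L
    }
    ped <- rbind(ped, data.frame(
      family_id = ped$family_id[i], individual_id = new_id,
      father_id = "0", mother_id = "0", sex = new_sex,
      stringsAsFactors = FALSE
    ))
  }
  ped
}

#' Read / write ped files
#'
#' Whitespace-delimited, five columns: FID IID FATHER MOTHER SEX, with 0 for
#' a missing parent.
#'
#' @param path file path.
#' @return `read_ped` returns a [pedigree]; `write_ped` returns `path`
#'   invisibly.
#' @export
read_ped <- function(path) {
  tab <- utils::read.table(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 5) stop("ped file must have >= 5 columns (FID IID FATHER MOTHER SEX)")
  pedigree(tab[[1]], tab[[2]], tab[[3]], tab[[4]], as.integer(tab[[5]]))
}

#' @rdname read_ped
#' @param ped a [pedigree].
#' @export
write_ped <- function(ped, path) {
  utils::write.table(as.data.frame(ped)[, c("family_id", "individual_id",
                                            "father_id", "mother_id", "sex")],
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Validate a pedigree
#'
#' Report-only check for structural problems: parentage cycles, parents with
#' inconsistent sex, parent ids that do not correspond to any record, and
#' duplicate individual ids.
#'
#' @param ped a [pedigree] or equivalent data.frame.
#' @return A list with logical `ok` and character vectors `cycles`,
#'   `sex_inconsistent`, `dangling_parents`, `duplicates`.
#' @export
validate_pedigree <- function(ped) {
  ids <- ped$individual_id
  dup <- unique(ids[duplicated(ids)])
  sex_of <- stats::setNames(ped$sex, ids)
  fathers <- setdiff(unique(ped$father_id), "0")
  mothers <- setdiff(unique(ped$mother_id), "0")
  dangling <- setdiff(c(fathers, mothers), ids)
  sex_bad <- c(fathers[!is.na(sex_of[fathers]) & sex_of[fathers] != 1L],
               mothers[!is.na(sex_of[mothers]) & sex_of[mothers] != 2L])

  # cycle detection: depth-first over the parent relation
  parent_of <- function(id) {
    r <- ped[match(id, ids), c("father_id", "mother_id")]
    setdiff(unlist(r, use.names = FALSE), "0")
  }
  state <- stats::setNames(rep(0L, length(ids)), ids)  # 0 new, 1 open, 2 done
  cycles <- character(0)
  visit <- function(id) {
    if (!id %in% ids) return(invisible())
    if (state[[id]] == 1L) { cycles <<- c(cycles, id); return(invisible()) }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (p in parent_of(id)) visit(p)
    state[[id]] <<- 2L
  }
  for (id in ids) visit(id)

  res <- list(ok = length(dup) == 0 && length(dangling) == 0 &&
                length(sex_bad) == 0 && length(cycles) == 0,
              cycles = unique(cycles),
              sex_inconsistent = unique(sex_bad),
              dangling_parents = dangling,
              duplicates = dup)
  res
}

# topological order: parents before children; errors on cycles
pedigree_topo_order <- function(ped) {
  ids <- ped$individual_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]; mo <- idx[ped$mother_id]  # NA for missing/founder
  placed <- rep(FALSE, n)
  order_out <- integer(0)
  repeat {
    ready <- !placed & (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
                       (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    order_out <- c(order_out, which(ready))
    placed[ready] <- TRUE
  }
  if (length(order_out) < n)
    stop("pedigree contains a parentage cycle involving: ",
         paste(ids[!placed], collapse = ", "))
  order_out
}

#' Expected relatedness (2*phi) matrix from a pedigree
#'
#' Computes kinship coefficients by the standard recursion over a
#' parents-before-children ordering -- phi(i,i) = (1 + phi(f_i, m_i)) / 2 and
#' phi(i,j) = (phi(f_i, j) + phi(m_i, j)) / 2 -- under the usual convention
#' that founders are non-inbred and mutually unrelated, and returns twice the
#' kinship coefficient (the additive-genetic covariance structure; non-inbred
#' self = 1, parent-offspring and full sibs = 0.5).
#'
#' @param ped a [pedigree].
#' @return A `kinship_matrix`: an N x N symmetric numeric matrix of 2*phi
#'   values with individual ids as dimnames.
#' @export
compute_kinship <- function(ped) {
  v <- validate_pedigree(ped)
  if (length(v$cycles) > 0)
    stop("cannot compute kinship: cycle at ", paste(v$cycles, collapse = ", "))
  if (length(v$dangling_parents) > 0)
    stop("cannot compute kinship: unknown parent ids ",
         paste(v$dangling_parents, collapse = ", "))
  ord <- pedigree_topo_order(ped)
  ids <- ped$individual_id
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]; mo <- idx[ped$mother_id]
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in ord) {
    f <- fa[i]; m <- mo[i]
    if (is.na(f) && is.na(m)) {          # founder
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[f, m])
      earlier <- ord[seq_len(which(ord == i) - 1L)]
      if (length(earlier)) {
        val <- 0.5 * (phi[f, earlier] + phi[m, earlier])
        phi[i, earlier] <- val
        phi[earlier, i] <- val
      }
    }
  }
  k <- 2 * phi
  class(k) <- c("kinship_matrix", "matrix", "array")
  k
}

#' Remove or merge monozygotic twins
#'
#' MZ twins are genetically identical and make the expected-relatedness
#' matrix (near-)singular. `mode = "drop-one"` removes the second-listed twin
#' of each pair from the pedigree before computing kinship. `mode = "merge"`
#' keeps both but sets their mutual 2*phi entry to the self entry of the
#' first twin (documented alternative; the resulting matrix is singular by
#' construction).
#'
#' @param ped a [pedigree].
#' @param mz_pairs list of length-2 character vectors of individual ids; each
#'   pair must share both parents.
#' @param mode `"drop-one"` or `"merge"`.
#' @return list with the (possibly reduced) `pedigree` and the
#'   `kinship` matrix.
#' @export
handle_mz_twins <- function(ped, mz_pairs, mode = c("drop-one", "merge")) {
  mode <- match.arg(mode)
  for (pair in mz_pairs) {
    r <- ped[match(pair, ped$individual_id), ]
    if (anyNA(r$individual_id)) stop("MZ pair member not in pedigree")
    if (r$father_id[1] != r$father_id[2] || r$mother_id[1] != r$mother_id[2])
      stop("MZ pair ", paste(pair, collapse = "/"), " does not share both parents")
  }
  if (length(mz_pairs) == 0 || mode == "drop-one") {
    drop <- vapply(mz_pairs, `[`, character(1), 2L)
    keep <- !(ped$individual_id %in% drop)
    used_as_parent <- drop[drop %in% c(ped$father_id, ped$mother_id)]
    if (length(used_as_parent))
      stop("cannot drop twin(s) that appear as parents: ",
           paste(used_as_parent, collapse = ", "))
    ped2 <- ped[keep, , drop = FALSE]
    class(ped2) <- class(ped)
    return(list(pedigree = ped2, kinship = compute_kinship(ped2)))
  }
  k <- compute_kinship(ped)
  for (pair in mz_pairs) {
    k[pair[1], pair[2]] <- k[pair[2], pair[1]] <- k[pair[1], pair[1]]
    k[pair[2], pair[2]] <- k[pair[1], pair[1]]
  }
  list(pedigree = ped, kinship = k)
}

#' Write a kinship matrix as TSV and as a sparse triplet list
#'
#' @param k a `kinship_matrix`.
#' @param path output path for the dense TSV (ids as header and first
#'   column).
#' @param sparse_path optional path for a 3-column (id1, id2, 2phi) list of
#'   the nonzero upper triangle.
#' @export
write_kinship <- function(k, path, sparse_path = NULL) {
  df <- data.frame(individual_id = rownames(k), as.data.frame(unclass(k)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sparse_path)) {
    up <- which(upper.tri(k, diag = TRUE) & k != 0, arr.ind = TRUE)
    utils::write.table(
      data.frame(id1 = rownames(k)[up[, 1]], id2 = colnames(k)[up[, 2]],
                 phi2 = k[up]),
      sparse_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
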