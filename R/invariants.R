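#' Minimal semi-positive transition invariants
#'
#' A transition invariant (TI) is a non-negative integer Parikh vector x with
#' \eqn{C x = 0}: firing every transition of the invariant the prescribed
#' number of times reproduces any marking exactly. TIs are the steady-state
#' flows of the net; in metabolic nets they coincide with elementary modes.
#' Returned invariants are minimal-support, gcd-normalised, and sorted
#' canonically (support size, then lexicographic support ids). The set is
#' complete: every semi-positive integer solution is a non-negative rational
#' combination of the returned vectors.
#'
#' The computation is Farkas/Fourier-Motzkin column elimination on
#' \eqn{[C^T | I]}: constraints (places) are eliminated one at a time, keeping
#' all non-negative pairwise combinations, with intermediate and final
#' minimal-support filtering. All arithmetic is exact integer arithmetic on
#' doubles with an overflow guard at 2^49; rows are gcd-reduced at every step
#' to keep entries small.
#'
#' @param net a `petri_net`
#' @return list of `transition_invariant` objects, each with `coefficients`
#'   (named positive integers over the support) and `support`
#' @export
transition_invariants <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  if (nrow(net$transitions) == 0L) .stopf("net has no transitions")
  C <- incidence_matrix(net)
  sol <- .farkas_minimal(t(C))
  .as_invariants(sol, colnames(C), "transition_invariant")
}

#' Minimal semi-positive place invariants
#'
#' A place invariant (PI) is a non-negative integer vector y with
#' \eqn{y C = 0}: the weighted token sum \eqn{y \cdot m} is conserved by every
#' firing, so a PI describes substance conservation (e.g. a gene that is
#' bound and released but never produced or degraded). Same algorithm and
#' normalisation as [transition_invariants()].
#'
#' @param net a `petri_net`
#' @return list of `place_invariant` objects
#' @export
place_invariants <- function(net) {
  stopifnot(inherits(net, "petri_net"))
  if (nrow(net$places) == 0L) .stopf("net has no places")
  C <- incidence_matrix(net)
  sol <- .farkas_minimal(C)
  .as_invariants(sol, rownames(C), "place_invariant")
}

# M: n x k. Finds all minimal-support x >= 0 (length n) with x %*% M == 0.
.farkas_minimal <- function(M) {
  n <- nrow(M); k <- ncol(M)
  B <- cbind(diag(n), M)
  # Eliminate sparser constraint columns first to limit intermediate blow-up.
  dens <- colSums(M != 0)
  for (j in (n + order(dens, method = "radix"))) {
    col <- B[, j]
    keep <- B[col == 0, , drop = FALSE]
    pos <- which(col > 0); neg <- which(col < 0)
    if (length(pos) && length(neg)) {
      combos <- vector("list", length(pos) * length(neg))
      idx <- 0L
      for (ip in pos) {
        for (ineg in neg) {
          idx <- idx + 1L
          r <- (-col[ineg]) * B[ip, ] + col[ip] * B[ineg, ]
          .check_exact(r, "invariants")
          g <- .gcd_vec(r)
          if (g > 1) r <- r / g
          combos[[idx]] <- r
        }
      }
      keep <- rbind(keep, do.call(rbind, combos))
    }
    if (nrow(keep)) {
      keep <- keep[!duplicated(keep), , drop = FALSE]
      keep <- .filter_minimal_support(keep, n)
    }
    B <- keep
    if (nrow(B) == 0L) break
  }
  if (nrow(B) == 0L) return(matrix(0, 0, n))
  X <- B[, seq_len(n), drop = FALSE]
  X <- X[rowSums(X) > 0, , drop = FALSE]
  if (nrow(X) == 0L) return(matrix(0, 0, n))
  X <- t(apply(X, 1, function(r) r / .gcd_vec(r)))
  X <- X[!duplicated(X), , drop = FALSE]
  .filter_minimal_support(X, n)
}

# Drop rows whose support (within the first n columns) strictly contains the
# support of another row. Rows with equal support are both kept: after gcd
# normalisation, proportional rows are identical and removed by dedup.
.filter_minimal_support <- function(B, n) {
  nr <- nrow(B)
  if (nr <= 1L) return(B)
  S <- B[, seq_len(n), drop = FALSE] != 0
  sz <- rowSums(S)
  ord <- order(sz, method = "radix")
  S <- S[ord, , drop = FALSE]
  B <- B[ord, , drop = FALSE]
  sz <- sz[ord]
  drop <- logical(nr)
  for (i in seq_len(nr - 1L)) {
    if (drop[i]) next
    si <- S[i, ]
    cand <- which(!drop & sz > sz[i])
    if (length(cand) == 0L) next
    miss <- rowSums(matrix(si, nrow = length(cand), ncol = ncol(S), byrow = TRUE) &
                      !S[cand, , drop = FALSE])
    # row j is a strict superset of row i's support when nothing of si is missing
    if (any(miss == 0)) drop[cand[miss == 0]] <- TRUE
  }
  B[!drop, , drop = FALSE]
}

.as_invariants <- function(X, ids, cls) {
  if (nrow(X) == 0L) return(list())
  colnames(X) <- ids
  inv <- lapply(seq_len(nrow(X)), function(i) {
    x <- X[i, ]
    sup <- sort(ids[x > 0], method = "radix")
    structure(list(coefficients = x[sup], support = sup), class = cls)
  })
  # canonical order: support size, then lexicographic support ids
  key <- vapply(inv, function(v)
    sprintf("%06d|%s", length(v$support), paste(v$support, collapse = ",")),
    character(1))
  inv <- inv[order(key, method = "radix")]
  for (i in seq_along(inv)) inv[[i]]$index <- i
  inv
}

#' @export
print.transition_invariant <- function(x, ...) {
  cat(sprintf("<TI%s> %s\n",
              if (!is.null(x$index)) paste0("_", x$index) else "",
              paste(sprintf("%s:%g", names(x$coefficients), x$coefficients),
                    collapse = " ")))
  invisible(x)
}

#' @export
print.place_invariant <- function(x, ...) {
  cat(sprintf("<PI%s> %s\n",
              if (!is.null(x$index)) paste0("_", x$index) else "",
              paste(sprintf("%s:%g", names(x$coefficients), x$coefficients),
                    collapse = " ")))
  invisible(x)
}

#' Full-length coefficient vector of an invariant
#'
#' @param inv a `transition_invariant` or `place_invariant`
#' @param ids full id vector to expand over
#' @return named numeric vector over `ids`
#' @export
invariant_vector <- function(inv, ids) {
  x <- stats::setNames(numeric(length(ids)), ids)
  x[names(inv$coefficients)] <- inv$coefficients
  x
}

#' Invariant coverage diagnostics
#'
#' A net is covered by TIs (CTI) when every transition lies in the support of
#' at least one TI — the standard structural consistency criterion: a
#' transition in no invariant can never fire at steady state and hints at a
#' modelling error. CPI is the analogue for places; open systems (with
#' synthesis and degradation) are typically far from CPI.
#'
#' @param net a `petri_net`
#' @param tis list from [transition_invariants()]
#' @param pis list from [place_invariants()]
#' @return list with `is_CTI`, `is_CPI`, `covered_transitions`,
#'   `covered_places`, `uncovered_transitions`, `uncovered_places`
#' @export
coverage <- function(net, tis, pis) {
  ct <- .sort_ids(unique(unlist(lapply(tis, `[[`, "support"))))
  cp <- .sort_ids(unique(unlist(lapply(pis, `[[`, "support"))))
  ut <- setdiff(net$transitions$id, ct)
  up <- setdiff(net$places$id, cp)
  list(is_CTI = length(ut) == 0L, is_CPI = length(up) == 0L,
       covered_transitions = ct, covered_places = cp,
       uncovered_transitions = sort(ut, method = "radix"),
       uncovered_places = sort(up, method = "radix"))
}

#' Export invariants to JSON or TSV
#'
#' @param invs list of invariants
#' @param path output path; format chosen by extension (`.json` or `.tsv`)
#' @return `path`, invisibly
#' @export
write_invariants <- function(invs, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- lapply(invs, function(v)
      list(index = v$index, support = v$support,
           coefficients = as.list(v$coefficients)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "tsv") {
    rows <- lapply(invs, function(v)
      data.frame(index = v$index,
                 id = names(v$coefficients),
                 coefficient = unname(v$coefficients)))
    utils::write.table(do.call(rbind, rows), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else .stopf("unsupported invariant export format: .%s", ext)
  invisible(path)
}

#' Import externally computed invariants from JSON
#'
#' For cross-checking against other invariant tools.
#'
#' @param path JSON file written by [write_invariants()] or an external tool
#'   emitting `[{index, support, coefficients}, ...]`
#' @param type "transition" or "place"
#' @return list of invariant objects
#' @export
read_invariants <- function(path, type = c("transition", "place")) {
  type <- match.arg(type)
  cls <- paste0(type, "_invariant")
  obj <- jsonlite::read_json(path)
  lapply(obj, function(v) {
    co <- unlist(v$coefficients)
    sup <- sort(names(co)[co > 0], method = "radix")
    structure(list(coefficients = co[sup], support = sup,
                   index = v$index %||% NA_integer_), class = cls)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
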