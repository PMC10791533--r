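#' Construct a pedigree
#'
#' A pedigree is a trio table `id`, `sire`, `dam` (`NA` = unknown parent).
#' Parents referenced but not listed as rows are added as founders. Founders
#' (both parents unknown) are assumed mutually unrelated and non-inbred.
#' The structure must be acyclic.
#'
#' @param df data.frame with columns `id`, `sire`, `dam`.
#' @return an object of class `pedigree`: the trio table plus a kinship
#'   memo environment and per-individual generation numbers.
#' @export
pedigree <- function(df) {
  if (!all(c("id", "sire", "dam") %in% names(df))) {
    stop("pedigree: need columns id, sire, dam")
  }
  df <- data.frame(id = as.character(df$id), sire = as.character(df$sire),
                   dam = as.character(df$dam), stringsAsFactors = FALSE)
  df$sire[df$sire %in% c("", "0")] <- NA_character_
  df$dam[df$dam %in% c("", "0")] <- NA_character_
  if (anyDuplicated(df$id)) stop("pedigree: duplicated ids")
  refs <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$id)
  if (length(refs)) {
    df <- rbind(df, data.frame(id = refs, sire = NA_character_, dam = NA_character_,
                               stringsAsFactors = FALSE))
  }
  n <- nrow(df)
  idx <- seq_len(n); names(idx) <- df$id
  si <- ifelse(is.na(df$sire), NA_integer_, idx[df$sire])
  di <- ifelse(is.na(df$dam), NA_integer_, idx[df$dam])

  # generation numbers by iterative relaxation; non-convergence implies a cycle
  gen <- rep(0L, n)
  for (pass in seq_len(n + 1L)) {
    new <- pmax(ifelse(is.na(si), -1L, gen[ifelse(is.na(si), 1L, si)]),
                ifelse(is.na(di), -1L, gen[ifelse(is.na(di), 1L, di)])) + 1L
    new <- pmax(new, 0L)
    if (all(new == gen)) break
    if (pass > n) stop("pedigree: cycle detected")
    gen <- new
  }
  structure(list(tab = df, sire = si, dam = di, index = idx, gen = gen,
                 memo = new.env(parent = emptyenv())),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", nrow(x$tab), "individuals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  invisible(x)
}

#' Pedigree founders
#' @param ped a [pedigree()].
#' @return character vector of ids with both parents unknown.
#' @export
founders <- function(ped) ped$tab$id[is.na(ped$sire) & is.na(ped$dam)]

.ped_index <- function(ped, id) {
  i <- ped$index[id]
  if (is.na(i)) stop("pedigree: unknown id: ", id)
  unname(i)
}

.kinship_idx <- function(ped, a, b) {
  key <- if (a <= b) paste0(a, "|", b) else paste0(b, "|", a)
  hit <- ped$memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (a == b) {
    sa <- ped$sire[a]; da <- ped$dam[a]
    f <- if (is.na(sa) || is.na(da)) 0 else .kinship_idx(ped, sa, da)
    0.5 * (1 + f)
  } else {
    # recurse on the individual further from the founders; it cannot be an
    # ancestor of the other, so the standard recursion is valid
    if (ped$gen[a] < ped$gen[b]) { tmp <- a; a <- b; b <- tmp }
    sa <- ped$sire[a]; da <- ped$dam[a]
    0.5 * ((if (is.na(sa)) 0 else .kinship_idx(ped, sa, b)) +
           (if (is.na(da)) 0 else .kinship_idx(ped, da, b)))
  }
  assign(key, val, envir = ped$memo)
  val
}

#' Coefficient of kinship
#'
#' Probability that one allele drawn at random from each of `a` and `b` is
#' identical by descent, under the assumption that founders are unrelated and
#' non-inbred. Computed by the classic recursion
#' theta(a, b) = (theta(sire_a, b) + theta(dam_a, b)) / 2 with
#' theta(x, x) = (1 + F_x) / 2; a missing parent contributes zero.
#'
#' @param ped a [pedigree()].
#' @param a,b individual ids.
#' @return kinship coefficient in `[0, (1 + max F) / 2]`.
#' @export
kinship <- function(ped, a, b) {
  .kinship_idx(ped, .ped_index(ped, a), .ped_index(ped, b))
}

#' Pedigree inbreeding coefficient
#'
#' Kinship of the individual's parents; 0 when either parent is unknown.
#' @inheritParams kinship
#' @param id individual id.
#' @export
inbreeding <- function(ped, id) {
  i <- .ped_index(ped, id)
  if (is.na(ped$sire[i]) || is.na(ped$dam[i])) return(0)
  .kinship_idx(ped, ped$sire[i], ped$dam[i])
}

#' Expected (pedigree) relatedness
#'
#' The coefficient of relationship
#' r = 2 theta(a,b) / sqrt((1 + F_a)(1 + F_b)),
#' which reduces to twice the kinship when both individuals are outbred.
#' Founder pairs have r = 0 by the founder-unrelatedness assumption.
#'
#' @inheritParams kinship
#' @return relatedness in `[0, 1]`.
#' @export
expected_relatedness <- function(ped, a, b) {
  if (identical(a, b)) stop("expected_relatedness: a and b must differ")
  th <- kinship(ped, a, b)
  2 * th / sqrt((1 + inbreeding(ped, a)) * (1 + inbreeding(ped, b)))
}

#' Pedigree depth
#'
#' Number of complete ancestral generations: 0 if either parent is unknown,
#' otherwise `1 + min(depth(sire), depth(dam))`. Depth d means every ancestor
#' through generation d is recorded while some ancestor at generation d + 1
#' is not.
#'
#' @inheritParams inbreeding
#' @return non-negative integer.
#' @export
pedigree_depth <- function(ped, id) {
  i <- .ped_index(ped, id)
  depth_idx <- function(i) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (is.na(s) || is.na(d)) return(0L)
    1L + min(depth_idx(s), depth_idx(d))
  }
  depth_idx(i)
}

#' Detect cryptic relatives
#'
#' Pairs that are unconnected on the pedigree (expected relatedness exactly 0,
#' including founder-founder pairs) but whose genetic relatedness falls inside
#' `[low, high]` — the signature of a recent pedigree link the records missed.
#'
#' @param genetic_r data.frame with columns `a`, `b`, `r` (genetic
#'   relatedness per pair).
#' @param ped a [pedigree()] covering all ids in `genetic_r`.
#' @param low,high inclusive band of genetic relatedness flagged as cryptic
#'   (defaults 0.1 and 0.35).
#' @return the subset of `genetic_r` rows flagged as cryptic pairs, with an
#'   added `pedigree_r` column (all zero by construction).
#' @export
find_cryptic_pairs <- function(genetic_r, ped, low = 0.1, high = 0.35) {
  stopifnot(all(c("a", "b", "r") %in% names(genetic_r)))
  ped_r <- vapply(seq_len(nrow(genetic_r)), function(i) {
    expected_relatedness(ped, genetic_r$a[i], genetic_r$b[i])
  }, numeric(1))
  keep <- ped_r == 0 & genetic_r$r >= low & genetic_r$r <= high
  out <- genetic_r[keep, , drop = FALSE]
  out$pedigree_r <- rep(0, nrow(out))
  rownames(out) <- NULL
  out
}

#' Documented inbreeding among offspring
#'
#' Counts offspring whose recorded parents are connected on the pedigree
#' (expected relatedness > 0) and reports the proportion in percent. Offspring
#' with an unknown sire are excluded (their parent pair cannot be assessed).
#'
#' @param parentage data.frame with `offspring_id`, `mother_id`, `sire_id`.
#' @param ped a [pedigree()].
#' @return list with `n_offspring`, `n_inbred`, `proportion` (percent) and
#'   `inbred_offspring` (ids with their parents' pedigree relatedness).
#' @export
inbreeding_summary <- function(parentage, ped) {
  known <- parentage[!is.na(parentage$sire_id) & !is.na(parentage$mother_id), , drop = FALSE]
  r <- vapply(seq_len(nrow(known)), function(i) {
    expected_relatedness(ped, known$mother_id[i], known$sire_id[i])
  }, numeric(1))
  inbred <- known$offspring_id[r > 0]
  list(n_offspring = nrow(known),
       n_inbred = length(inbred),
       proportion = 100 * length(inbred) / nrow(known),
       inbred_offspring = stats::setNames(r[r > 0], inbred))
}
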