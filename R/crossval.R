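# Cross-validation split enumeration and label-permutation schemes.
#
# A split is a list with `train` and `test` data.frames of (run, condition)
# keys plus a `scheme` label. Splits are enumerated deterministically.

make_split <- function(train, test, scheme) {
  structure(list(train = train, test = test, scheme = scheme), class = "cv_split")
}

keys <- function(runs, conditions) {
  expand.grid(run = runs, condition = conditions, stringsAsFactors = FALSE,
              KEEP.OUT.ATTRS = FALSE)
}

#' Leave-two-identities-out cross-validation splits
#'
#' One split per (familiar, unfamiliar) identity pair: the classifier trains
#' on all runs of the remaining 3 + 3 identities and tests on all runs of the
#' left-out pair, so test identities are never seen in training. With 4 + 4
#' identities this yields the canonical 16 splits.
#'
#' @param familiar,unfamiliar disjoint identity label vectors (length >= 2).
#' @param runs run labels (default `1:11`).
#' @return list of splits (`scheme = "l2io"`).
#' @export
leave_two_identities_out_splits <- function(familiar, unfamiliar, runs = 1:11) {
  if (length(intersect(familiar, unfamiliar)) > 0)
    stop("an identity appears in both the familiar and unfamiliar lists")
  if (length(familiar) < 2 || length(unfamiliar) < 2)
    stop("need at least 2 identities per class")
  splits <- list()
  for (f in familiar) {
    for (u in unfamiliar) {
      test_ids <- c(f, u)
      train_ids <- c(setdiff(familiar, f), setdiff(unfamiliar, u))
      splits[[length(splits) + 1]] <-
        make_split(keys(runs, train_ids), keys(runs, test_ids), "l2io")
    }
  }
  splits
}

#' Leave-one-run-out cross-validation splits
#'
#' @param runs run labels (>= 2 runs).
#' @param conditions condition labels included in each side.
#' @return list of splits (`scheme = "loro"`), one per run.
#' @export
leave_one_run_out_splits <- function(runs, conditions) {
  if (length(runs) < 2) stop("leave-one-run-out needs at least 2 runs")
  lapply(runs, function(r)
    make_split(keys(setdiff(runs, r), conditions), keys(r, conditions), "loro"))
}

#' Exhaustive balanced familiarity label permutations
#'
#' All balanced assignments of half the identities to the "familiar" class,
#' deduplicated by label-complement equivalence (a relabeling and its
#' complement give identical accuracy for a symmetric binary classifier):
#' `choose(2k, k) / 2` permutations. With 8 identities this is the canonical
#' 35. The veridical labeling's equivalence class is included and listed
#' first when the true classes are supplied.
#'
#' @param identities vector of 2k identity labels.
#' @param familiar optional vector naming the truly familiar identities; used
#'   only to order the veridical labeling first.
#' @return list of named character vectors mapping identity to class.
#' @export
enumerate_familiarity_permutations <- function(identities, familiar = NULL) {
  n <- length(identities)
  if (n %% 2 != 0) stop("need an even number of identities")
  k <- n / 2
  sets <- combn(identities, k, simplify = FALSE)
  # complement dedup: keep the member of each pair that contains identities[1]
  sets <- Filter(function(s) identities[1] %in% s, sets)
  perms <- lapply(sets, function(s)
    setNames(ifelse(identities %in% s, "familiar", "unfamiliar"), identities))
  if (!is.null(familiar)) {
    veridical <- vapply(perms, function(p)
      setequal(names(p)[p == "familiar"], familiar) ||
        setequal(names(p)[p == "unfamiliar"], familiar), logical(1))
    perms <- c(perms[veridical], perms[!veridical])
  }
  perms
}

#' Random identity relabelings within each run
#'
#' Each permutation independently shuffles the identity labels within every
#' run (a bijection of the condition labels per run). Used to build the
#' identity-decoding null distribution (20 per subject in the canonical
#' analysis).
#'
#' @param conditions identity labels to shuffle (e.g. the 4 familiar ones).
#' @param runs run labels.
#' @param n_perms number of permutations (default 20).
#' @param seed integer seed; the list is deterministic given the seed.
#' @return list of data.frames with columns `run`, `condition`, `new_label`.
#' @export
identity_permutations_within_run <- function(conditions, runs, n_perms = 20,
                                             seed = 1L) {
  if (n_perms < 1) stop("n_perms must be >= 1")
  with_seed(seed, {
    lapply(seq_len(n_perms), function(p) {
      do.call(rbind, lapply(runs, function(r)
        data.frame(run = r, condition = conditions,
                   new_label = sample(conditions), stringsAsFactors = FALSE)))
    })
  })
}
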