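#' Theoretical digestion rule
#'
#' Trypsin/P specificity: cleavage after every K or R, including K/R-P
#' junctions (the proline rule is deliberately not applied).
#'
#' @param max_missed_cleavages maximum missed cleavages per peptide.
#' @param min_length,max_length retained peptide length bounds.
#' @return An object of class `digest_spec`.
#' @export
digest_spec <- function(max_missed_cleavages = 1L, min_length = 7L,
                        max_length = 52L) {
  stopifnot(max_missed_cleavages >= 0, min_length > 0,
            min_length <= max_length)
  structure(list(max_missed_cleavages = as.integer(max_missed_cleavages),
                 min_length = as.integer(min_length),
                 max_length = as.integer(max_length)),
            class = "digest_spec")
}

#' Theoretical tryptic digest of a protein sequence
#'
#' Returns the set of fully cleaved products and all products with up to
#' `max_missed_cleavages` internal missed cleavages, restricted to the length
#' bounds. Cleavage occurs after every K/R, including before proline.
#'
#' @param sequence amino-acid sequence (uppercase IUPAC letters).
#' @param spec a [digest_spec()].
#' @return Character vector of unique peptides.
#' @examples
#' theoretical_digest("AAKBBRCC", digest_spec(1, 2, 10))
#' @export
theoretical_digest <- function(sequence, spec = digest_spec()) {
  sequence <- toupper(sequence)
  if (!grepl("^[A-Z]*$", sequence))
    stop("sequence contains non-amino-acid characters")
  if (nchar(sequence) == 0) return(character(0))
  chars <- strsplit(sequence, "")[[1]]
  cut_after <- which(chars %in% c("K", "R"))
  bounds <- c(0, cut_after[cut_after < length(chars)], length(chars))
  bounds <- unique(bounds)
  n_frag <- length(bounds) - 1
  peps <- character(0)
  for (i in seq_len(n_frag)) {
    for (j in i:min(i + spec$max_missed_cleavages, n_frag)) {
      p <- substr(sequence, bounds[i] + 1, bounds[j + 1])
      if (nchar(p) >= spec$min_length && nchar(p) <= spec$max_length)
        peps <- c(peps, p)
    }
  }
  unique(peps)
}

#' Deterministic greedy parsimony grouping of peptides into protein groups
#'
#' Greedy set cover over accessions: repeatedly select the accession covering
#' the most not-yet-assigned peptides (ties broken by most total peptides,
#' then by lexicographically smallest accession). Non-selected accessions
#' whose peptide sets are subsets of a selected accession's set join that
#' group as members. Every peptide is assigned to exactly one group (the
#' earliest selected group containing it, giving the deterministic single
#' assignment needed for Hi3 summation). A retained group's lead accession is
#' its member with the most distinct peptides, ties lexicographic. Retained
#' groups lacking any peptide unique to the group (relative to the other
#' retained groups) are merged into the retained group sharing the most
#' peptides with them.
#'
#' @param peptide_map named list: peptide sequence -> character vector of
#'   accessions carrying that peptide.
#' @return List of protein groups, each a list with `lead`, `members`,
#'   `peptides` (assigned peptides), `unique_peptide_count` (peptides mapping
#'   only to accessions within the group). Output is invariant to input
#'   ordering. The attribute `"greedy_cover_size"` records the number of
#'   accessions the greedy cover selected before any unique-peptide merging,
#'   for comparison against minimal set covers.
#' @examples
#' parsimony_group(list(p1 = "A", p2 = c("A", "B"), p3 = "C"))
#' @export
parsimony_group <- function(peptide_map) {
  if (length(peptide_map) == 0) return(list())
  if (any(lengths(peptide_map) == 0))
    stop("every peptide must map to at least one accession")
  peptide_map <- peptide_map[order(names(peptide_map))]
  peps <- names(peptide_map)
  # accession -> peptide index sets
  acc_all <- sort(unique(unlist(peptide_map)))
  acc_sets <- lapply(acc_all, function(a)
    which(vapply(peptide_map, function(s) a %in% s, logical(1))))
  names(acc_sets) <- acc_all
  tot <- lengths(acc_sets)

  unassigned <- rep(TRUE, length(peps))
  selected <- character(0)
  assigned_group <- integer(length(peps))
  while (any(unassigned)) {
    newcov <- vapply(acc_sets, function(s) sum(unassigned[s]), integer(1))
    best <- max(newcov)
    cand <- names(newcov)[newcov == best]
    if (length(cand) > 1) cand <- cand[tot[cand] == max(tot[cand])]
    pick <- sort(cand)[1]
    g <- length(selected) + 1L
    selected <- c(selected, pick)
    idx <- acc_sets[[pick]]
    assigned_group[idx[unassigned[idx]]] <- g
    unassigned[idx] <- FALSE
  }

  # membership: non-selected accessions whose sets are subsets of a selected set
  members <- lapply(selected, function(a) a)
  for (a in setdiff(acc_all, selected)) {
    s <- acc_sets[[a]]
    for (g in seq_along(selected)) {
      if (all(s %in% acc_sets[[selected[g]]])) {
        members[[g]] <- c(members[[g]], a)
        break
      }
    }
  }

  build <- function(sel, members, assigned_group) {
    lapply(seq_along(sel), function(g) {
      mem <- sort(members[[g]])
      pep_idx <- which(assigned_group == g)
      # unique peptides: mapping only to accessions inside this group
      uniq <- sum(vapply(pep_idx, function(i)
        all(peptide_map[[i]] %in% mem), logical(1)))
      n_distinct <- vapply(mem, function(a)
        sum(assigned_group[acc_sets[[a]]] == g), integer(1))
      lead_cand <- mem[n_distinct == max(n_distinct)]
      list(lead = sort(lead_cand)[1], members = mem,
           peptides = peps[pep_idx], unique_peptide_count = uniq)
    })
  }
  groups <- build(selected, members, assigned_group)
  greedy_cover_size <- length(selected)

  # merge retained groups with no unique peptide into their closest neighbour
  repeat {
    uc <- vapply(groups, `[[`, numeric(1), "unique_peptide_count")
    bad <- which(uc == 0 & vapply(groups, function(g)
      length(g$peptides), integer(1)) > 0)
    if (length(bad) == 0 || length(groups) == 1) break
    b <- bad[1]
    shared <- vapply(seq_along(groups), function(g) {
      if (g == b) return(-1L)
      sum(vapply(groups[[b]]$peptides, function(p)
        any(peptide_map[[p]] %in% groups[[g]]$members), logical(1)))
    }, integer(1))
    tgt <- which.max(shared)
    keep_sel <- setdiff(seq_along(selected), b)
    members[[tgt]] <- c(members[[tgt]], members[[b]])
    assigned_group[assigned_group == b] <- tgt
    assigned_group <- match(assigned_group, keep_sel)
    selected <- selected[keep_sel]
    members <- members[keep_sel]
    groups <- build(selected, members, assigned_group)
  }
  attr(groups, "greedy_cover_size") <- greedy_cover_size
  groups
}

#' Histogram of protein-group sizes
#'
#' @param groups output of [parsimony_group()].
#' @return Named integer vector: member count -> number of groups. Counts sum
#'   to the number of groups.
#' @export
group_size_summary <- function(groups) {
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  tab <- table(sizes)
  stats::setNames(as.integer(tab), names(tab))
}
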