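#' Build a framework tree from the taxonomy columns of a trait table
#'
#' Constructs a rooted species-level tree of nested polytomies from the
#' classification recorded in the trait table: orders form a polytomy at the
#' root, families form polytomies within orders, genera within families, and
#' species are the tips. The genus is taken as the first whitespace-delimited
#' token of the species label. All edges get unit branch length; levels
#' occupied by a single child are collapsed with their length absorbed into
#' the child's edge, so every classified tip sits at depth 4 from the root.
#' Species whose order is unknown (`"UK"`) are attached directly at the root
#' polytomy with an edge spanning the full tree height, keeping every tip at
#' the same depth (the tree is ultrametric).
#'
#' @param records Data frame with columns `species`, `family`, `order`.
#' @return An `ape::phylo` tree whose tip labels are the species labels with
#'   whitespace replaced by underscores.
#' @export
tree_from_taxonomy <- function(records) {
  sp <- records$species
  if (anyDuplicated(sp)) {
    stop(sprintf("duplicate species labels: %s",
                 paste(unique(sp[duplicated(sp)]), collapse = ", ")),
         call. = FALSE)
  }
  tip <- .tip_label(sp)
  genus <- vapply(strsplit(trimws(sp), "[[:space:]]+"), `[[`, character(1), 1)
  fam <- as.character(records$family)
  ord <- as.character(records$order)

  known <- !(ord %in% "UK") & !(fam %in% "UK")
  # bottom-up assembly; each newick fragment carries its own edge length
  bump_len <- function(piece) {
    # add 1 to the outermost edge length of a newick fragment "...:L"
    len <- as.numeric(sub("^.*:", "", piece))
    paste0(sub(":[0-9.]+$", "", piece), ":", len + 1)
  }
  join <- function(pieces) {
    if (length(pieces) == 1L) return(bump_len(pieces))
    paste0("(", paste(pieces, collapse = ","), "):1")
  }

  root_children <- character(0)
  for (o in unique(ord[known])) {
    fam_pieces <- character(0)
    for (f in unique(fam[known & ord == o])) {
      sel_f <- known & ord == o & fam == f
      gen_pieces <- character(0)
      for (g in unique(genus[sel_f])) {
        tips <- paste0(tip[sel_f & genus == g], ":1")
        gen_pieces <- c(gen_pieces, join(tips))
      }
      fam_pieces <- c(fam_pieces, join(gen_pieces))
    }
    root_children <- c(root_children, join(fam_pieces))
  }
  # unknown placements join the root polytomy with an edge spanning the full
  # tree height, so all tips stay contemporaneous (the tree is ultrametric)
  if (any(!known)) {
    root_children <- c(root_children, paste0(tip[!known], ":4"))
  }
  if (length(root_children) < 2L) {
    stop("need at least two lineages to build a tree", call. = FALSE)
  }
  nwk <- paste0("(", paste(root_children, collapse = ","), ");")
  tree <- ape::read.tree(text = nwk)
  tree
}

#' Minimum continuous-character change on a tree (linear parsimony)
#'
#' Computes the minimum total absolute change of a continuous character over
#' a rooted tree (Farris/linear parsimony), the quantity produced by mapping
#' a continuous trait onto a phylogeny for a maximally parsimonious
#' arrangement in which each internal node carries an optimal interval of
#' values. Polytomies are handled natively.
#'
#' The implementation is an exact dynamic programme over the node cost
#' functions, which are convex piecewise-linear with breakpoints restricted
#' to the observed tip values; each parent/child transfer applies the
#' standard two-pass `min(f(y) + |x - y|)` relaxation.
#'
#' @param tree An `ape::phylo` tree (branch lengths are ignored; only the
#'   topology matters).
#' @param trait Named numeric vector of tip values covering every tip.
#' @return The parsimony length (total absolute change, in trait units).
#' @export
parsimony_steps_continuous <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  vals <- .match_tips(tree, trait)
  S <- sort(unique(vals))
  nS <- length(S)
  if (nS == 1L) return(0)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode

  ## relax(f): g[i] = min_j f[j] + |S[i] - S[j]|
  relax <- function(f) {
    g <- f
    for (i in 2:nS) g[i] <- min(g[i], g[i - 1] + (S[i] - S[i - 1]))
    for (i in (nS - 1):1) g[i] <- min(g[i], g[i + 1] + (S[i + 1] - S[i]))
    g
  }

  cost <- matrix(0, nnode, nS)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1]; child <- edges[e, 2]
    g <- if (child <= ntip) abs(S - vals[child]) else relax(cost[child, ])
    cost[parent, ] <- cost[parent, ] + g
  }
  root <- ntip + 1L
  min(cost[root, ])
}

.match_tips <- function(tree, trait) {
  if (is.null(names(trait))) {
    if (length(trait) != length(tree$tip.label)) {
      stop("unnamed trait vector must match the number of tips", call. = FALSE)
    }
    return(setNames(as.numeric(trait), tree$tip.label))
  }
  names(trait) <- .tip_label(names(trait))
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing)) {
    stop(sprintf("trait values missing for tips: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(trait))) stop("trait values must be finite", call. = FALSE)
  as.numeric(trait[tree$tip.label])
}

#' Consistency and retention indices for a continuous character
#'
#' `CI = m / s` and `RI = (g - s) / (g - m)`, where `s` is the observed
#' linear-parsimony length on the tree, `m = max(x) - min(x)` is the minimum
#' length attainable on any tree (the trait range), and `g` is the
#' worst-case length, taken as the star-tree cost
#' `sum(|x_i - median(x)|)` -- the continuous analogue of the discrete
#' worst-case step count. CI = 1 means no homoplasy; RI near 1 means the
#' tree retains the character well.
#'
#' @param tree An `ape::phylo` tree.
#' @param trait Named numeric vector of tip values (must not be constant).
#' @return A list with `ci`, `ri`, `steps`, `min_steps`, `max_steps`.
#' @export
ci_ri <- function(tree, trait) {
  vals <- .match_tips(tree, trait)
  m <- diff(range(vals))
  if (m == 0) stop("trait is constant: CI undefined", call. = FALSE)
  s <- parsimony_steps_continuous(tree, trait)
  g <- sum(abs(vals - median(vals)))
  ri <- if (g > m) (g - s) / (g - m) else NA_real_
  list(ci = m / s, ri = ri, steps = s, min_steps = m, max_steps = g)
}

#' Blomberg's K with randomization test
#'
#' The variance-ratio statistic of Blomberg, Garland & Ives comparing the
#' observed partitioning of trait variance on the tree with its Brownian
#' expectation; K is near 1 under Brownian motion and near 0 when trait
#' values are unrelated to phylogeny. Significance is assessed by shuffling
#' tip values (`n_perm` permutations). Computation is delegated to
#' `phytools::phylosig`, the standard implementation in the field.
#'
#' @param tree An `ape::phylo` tree with positive branch lengths.
#' @param trait Named numeric vector of tip values (> 3 tips required).
#' @param n_perm Number of tip-shuffling randomizations (default 1000).
#' @param seed Optional integer seed for the randomization.
#' @return A list with `k`, `p` and `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 1000, seed = NULL) {
  vals <- .match_tips(tree, trait)
  if (length(vals) <= 3) {
    stop("need more than 3 tips to estimate K", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- phytools::phylosig(tree, setNames(vals, tree$tip.label),
                            method = "K", test = TRUE, nsim = n_perm)
  list(k = unname(res$K), p = unname(res$P), n_perm = n_perm)
}

#' Pagel's lambda with likelihood-ratio test
#'
#' Maximum-likelihood estimate of the multiplier lambda on the off-diagonal
#' entries of the Brownian tip covariance, constrained to `[0, 1]`, with a
#' likelihood-ratio test against the no-signal null (lambda = 0) on one
#' chi-squared degree of freedom. Computation is delegated to
#' `phytools::phylosig`; estimates that the unconstrained optimizer places
#' above 1 are evaluated at the lambda = 1 bound.
#'
#' @param tree An `ape::phylo` tree with positive branch lengths.
#' @param trait Named numeric vector of tip values.
#' @return A list with `lambda`, `logL`, `logL0` and `p`.
#' @export
pagel_lambda <- function(tree, trait) {
  vals <- .match_tips(tree, trait)
  if (length(vals) <= 3) {
    stop("need more than 3 tips to estimate lambda", call. = FALSE)
  }
  res <- phytools::phylosig(tree, setNames(vals, tree$tip.label),
                            method = "lambda", test = TRUE)
  lam <- res$lambda; ll <- res$logL
  if (lam > 1) {
    lam <- 1
    ll <- res$lik(1)
  }
  if (ll < res$logL0) {
    # optimizer landed below the lambda = 0 likelihood: the MLE is at the
    # boundary
    lam <- 0
    ll <- res$logL0
  }
  lrt <- max(2 * (ll - res$logL0), 0)
  list(lambda = max(lam, 0), logL = ll, logL0 = res$logL0,
       p = pchisq(lrt, df = 1, lower.tail = FALSE))
}

#' Phylogenetic-signal summary for the community traits
#'
#' Runs the full signal battery -- linear-parsimony steps, consistency and
#' retention indices, Blomberg's K with randomization p, Pagel's lambda with
#' likelihood-ratio p -- for the VOC index and the four reflectance band
#' indices on a species-level tree.
#'
#' @param records Trait table as returned by [load_trait_table()].
#' @param tree Optional `ape::phylo`; defaults to the framework tree built
#'   from the table's taxonomy with [tree_from_taxonomy()].
#' @param n_perm Randomizations for the K test.
#' @param seed Optional seed for the K randomizations.
#' @return A data frame with one row per trait and columns `trait`, `steps`,
#'   `ci`, `ri`, `k`, `k_p`, `lambda`, `lambda_p`.
#' @export
phylo_signal_table <- function(records, tree = NULL, n_perm = 1000,
                               seed = NULL) {
  if (is.null(tree)) tree <- tree_from_taxonomy(records)
  traits <- list(
    voc = voc_index(records$voc),
    uv = records$uv_reflectance, blue = records$blue_reflectance,
    green = records$green_reflectance, red = records$red_reflectance
  )
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(traits), function(tr) {
    x <- setNames(traits[[tr]], records$species)
    pars <- ci_ri(tree, x)
    k <- blomberg_k(tree, x, n_perm = n_perm)
    l <- pagel_lambda(tree, x)
    data.frame(trait = tr, steps = pars$steps, ci = pars$ci, ri = pars$ri,
               k = k$k, k_p = k$p, lambda = l$lambda, lambda_p = l$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
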