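## Synthetic-data generators: Yule trees, GTR+G+I alignments (optionally with
## lineage-specific GC drift), NNI-perturbed pseudo-posterior tree samples
## with injected rogues, and sparse presence matrices.  All generators are
## reproducible under a fixed seed.

#' Substitution-model parameters for sequence simulation
#'
#' @param rates Six GTR exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT (normalised internally; `rep(1, 6)` with equal frequencies is
#'   Jukes-Cantor).
#' @param baseFreq Stationary base frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape for among-site rate variation (4 equal-probability
#'   discrete categories).  `Inf` disables rate variation.
#' @param pInv Proportion of invariant sites in `[0, 1)`.
#' @param length Number of sites.
#' @param rateMultiplier Overall rate scaler (branch lengths are expected
#'   substitutions per site at multiplier 1).
#' @param gcDrift Lineage-specific GC drift rate: along each edge the GC
#'   share of the stationary frequencies moves on the logit scale by
#'   `drift * branch length` in a per-edge random direction.  0 disables
#'   drift (composition stationary across lineages).
#' @param seed Optional integer seed.
#' @return A validated parameter list of class `simulationParams`.
#' @export
simulationParams <- function(rates = rep(1, 6),
                             baseFreq = rep(0.25, 4),
                             alpha = 1, pInv = 0, length = 1000,
                             rateMultiplier = 1, gcDrift = 0, seed = NULL) {
    stopifnot(length(rates) == 6L, all(rates >= 0), any(rates > 0),
              length(baseFreq) == 4L, all(baseFreq > 0),
              alpha > 0, pInv >= 0, pInv < 1, length >= 1,
              rateMultiplier >= 0, gcDrift >= 0)
    if (abs(sum(baseFreq) - 1) > 1e-8)
        stop("base frequencies must sum to 1")
    structure(list(rates = rates / sum(rates), baseFreq = baseFreq,
                   alpha = alpha, pInv = pInv, length = as.integer(length),
                   rateMultiplier = rateMultiplier, gcDrift = gcDrift,
                   seed = seed),
              class = "simulationParams")
}

#' Simulate a Yule tree with exponential branch lengths
#'
#' @param nLeaves Number of leaves (>= 4).
#' @param seed Optional integer seed (fixed seed gives a fixed tree).
#' @param meanBranchLength Mean of the exponential branch-length draws.
#' @return An unrooted-interpretable binary `phylo` tree with tip labels
#'   `t1..tn`.
#' @export
simTree <- function(nLeaves, seed = NULL, meanBranchLength = 0.1) {
    if (nLeaves < 4L) stop("need at least 4 leaves")
    if (!is.null(seed)) set.seed(seed)
    phy <- ape::rphylo(nLeaves, birth = 1, death = 0)
    phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / meanBranchLength)
    phy$node.label <- NULL
    phy
}

## GTR rate matrix from exchangeabilities and frequencies, scaled so the
## expected substitution rate at stationarity is 1.
.gtr_Q <- function(rates, pi) {
    Q <- matrix(0, 4, 4, dimnames = list(.DNA_BASES, .DNA_BASES))
    pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
    for (k in 1:6) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        Q[i, j] <- rates[k] * pi[j]
        Q[j, i] <- rates[k] * pi[i]
    }
    diag(Q) <- -rowSums(Q)
    Q / sum(pi * -diag(Q))
}

## P(t) for each rate in `rs`, via eigendecomposition of Q (computed once).
.trans_probs <- function(Q, t, rs) {
    eg <- eigen(Q)
    Vi <- solve(eg$vectors)
    lapply(rs, function(r) {
        P <- eg$vectors %*% diag(exp(eg$values * t * r)) %*% Vi
        P <- pmax(Re(P), 0)
        P / rowSums(P)
    })
}

.shift_gc <- function(pi, gc_new) {
    gc_old <- pi[2] + pi[3]
    at_old <- pi[1] + pi[4]
    c(pi[1] * (1 - gc_new) / at_old, pi[2] * gc_new / gc_old,
      pi[3] * gc_new / gc_old, pi[4] * (1 - gc_new) / at_old)
}

#' Simulate a nucleotide alignment under GTR+G+I
#'
#' Site-wise simulation along a tree with branch lengths: each site is
#' invariant with probability `pInv`, otherwise carries one of four
#' equal-probability discrete-gamma rates.  With `gcDrift > 0` the stationary
#' frequencies drift in GC content independently along each lineage,
#' producing non-stationary composition.
#'
#' @param tree A `phylo` with branch lengths.
#' @param params A [simulationParams()] object.
#' @return An [Alignment-class] with one row per tip.
#' @examples
#' tr <- simTree(6, seed = 1)
#' aln <- simAlignment(tr, simulationParams(length = 200, seed = 1))
#' classifySites(aln)$variable
#' @export
simAlignment <- function(tree, params) {
    stopifnot(inherits(tree, "phylo"), inherits(params, "simulationParams"))
    if (is.null(tree$edge.length)) stop("tree needs branch lengths")
    if (!is.null(params$seed)) set.seed(params$seed)
    L <- params$length
    n_tip <- length(tree$tip.label)

    gam <- if (is.finite(params$alpha))
        phangorn::discrete.gamma(params$alpha, 4) else rep(1, 4)
    site_cat <- sample.int(4L, L, replace = TRUE)
    site_rate <- gam[site_cat]
    site_rate[stats::runif(L) < params$pInv] <- 0
    site_rate <- site_rate * params$rateMultiplier
    rate_groups <- split(seq_len(L), site_rate)
    group_rates <- as.numeric(names(rate_groups))

    phy <- stats::reorder(tree, "postorder")
    E <- phy$edge
    root <- E[nrow(E), 1L]
    n_node <- n_tip + phy$Nnode

    pi_node <- vector("list", n_node)
    pi_node[[root]] <- params$baseFreq
    states <- matrix(0L, n_node, L)
    states[root, ] <- sample.int(4L, L, replace = TRUE,
                                 prob = params$baseFreq)

    base_Q <- .gtr_Q(params$rates, params$baseFreq)
    for (k in rev(seq_len(nrow(E)))) {      # preorder
        p <- E[k, 1L]; ch <- E[k, 2L]; t_e <- phy$edge.length[k]
        pi_p <- pi_node[[p]]
        if (params$gcDrift > 0) {
            dir <- sample(c(-1, 1), 1L)
            gc <- stats::plogis(stats::qlogis(pi_p[2] + pi_p[3]) +
                                dir * params$gcDrift * t_e)
            pi_c <- .shift_gc(pi_p, gc)
            Q <- .gtr_Q(params$rates, pi_c)
        } else {
            pi_c <- pi_p
            Q <- base_Q
        }
        pi_node[[ch]] <- pi_c
        Ps <- .trans_probs(Q, t_e, group_rates)
        for (g in seq_along(rate_groups)) {
            idx <- rate_groups[[g]]
            sp <- states[p, idx]
            for (s in 1:4) {
                here <- idx[sp == s]
                if (!length(here)) next
                states[ch, here] <- sample.int(4L, length(here),
                                               replace = TRUE,
                                               prob = Ps[[g]][s, ])
            }
        }
    }
    m <- matrix(.DNA_BASES[states[seq_len(n_tip), , drop = FALSE]],
                n_tip, L, dimnames = list(phy$tip.label, NULL))
    alignment(m)
}

#' Simulate a pseudo-posterior tree sample
#'
#' Each tree is the true tree after `nniMoves` random nearest-neighbour
#' interchanges; afterwards each listed rogue leaf is pruned and reattached
#' at the midpoint of a uniformly chosen edge, with pendant branch length
#' equal to the median pendant length of the remaining tree.  A stand-in for
#' an MCMC tree sample with controllable discordance.
#'
#' @param tree True `phylo` tree with branch lengths.
#' @param nTrees Number of trees to generate.
#' @param nniMoves Non-negative integer: NNI perturbations per tree.
#' @param rogues Character vector of leaf labels to reattach at random.
#' @param seed Optional integer seed.
#' @return A [TreeSample-class].
#' @export
simTreeSample <- function(tree, nTrees, nniMoves = 0, rogues = character(0),
                          seed = NULL) {
    stopifnot(inherits(tree, "phylo"), nTrees >= 1, nniMoves >= 0)
    if (!all(rogues %in% tree$tip.label))
        stop("rogue labels not in tree: ",
             paste(setdiff(rogues, tree$tip.label), collapse = ", "))
    if (!is.null(seed)) set.seed(seed)
    trees <- vector("list", nTrees)
    for (i in seq_len(nTrees)) {
        t_i <- tree
        if (nniMoves > 0) t_i <- phangorn::rNNI(t_i, moves = nniMoves, n = 1)
        for (rg in rogues) t_i <- .reattach_random(t_i, rg)
        trees[[i]] <- t_i
    }
    treeSample(trees, origin = sprintf("simTreeSample(nni=%d, rogues=%d)",
                                       nniMoves, length(rogues)))
}

## Prune leaf `label` and reattach it at the midpoint of a uniformly random
## edge of the remaining tree.
.reattach_random <- function(phy, label) {
    bt <- ape::drop.tip(phy, label)
    pend <- bt$edge.length[bt$edge[, 2L] <= length(bt$tip.label)]
    plen <- stats::median(pend)
    j <- sample.int(nrow(bt$edge), 1L)
    tip <- structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = label, edge.length = plen,
                          Nnode = 1L), class = "phylo")
    ape::bind.tree(bt, tip, where = bt$edge[j, 2L],
                   position = bt$edge.length[j] / 2)
}

#' Simulate a sparse presence matrix
#'
#' Independent Bernoulli presence per cell at the target coverage.
#'
#' @param nTaxa Number of taxa.
#' @param genes Gene names (character) or a gene count.
#' @param targetCoverage Expected fraction of present cells, in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param nOutgroup Number of leading taxa tagged `outgroup` (default 0).
#' @return A [PresenceMatrix-class]; ingroup taxa carry cyclic `family` and
#'   `superfamily` tags so census operations are exercisable.
#' @export
simPresenceMatrix <- function(nTaxa, genes, targetCoverage, seed = NULL,
                              nOutgroup = 0) {
    stopifnot(targetCoverage > 0, targetCoverage <= 1, nTaxa >= 1)
    if (is.numeric(genes)) genes <- paste0("gene", seq_len(genes))
    if (!is.null(seed)) set.seed(seed)
    m <- matrix(stats::runif(nTaxa * length(genes)) < targetCoverage,
                nTaxa, length(genes),
                dimnames = list(sprintf("t%03d", seq_len(nTaxa)), genes))
    grp <- rep("ingroup", nTaxa)
    if (nOutgroup > 0) grp[seq_len(nOutgroup)] <- "outgroup"
    fam <- paste0("fam", (seq_len(nTaxa) - 1L) %% max(1L, nTaxa %/% 2L) + 1L)
    sup <- paste0("sup", (seq_len(nTaxa) - 1L) %% max(1L, nTaxa %/% 5L) + 1L)
    presenceMatrix(m, group = grp, family = fam, superfamily = sup)
}
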