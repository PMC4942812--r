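# Synthetic study generator: random metabolic networks, two-condition omics
# cohorts with planted gene-metabolite couplings, and clinical tables with
# planted hazard and ER links. Every stage of the pipeline can be validated
# against the returned ground truth.

#' Generate a random metabolic network
#'
#' Random bipartite-via-reactions wiring: each reaction draws 1-3 catalyzing
#' genes, 1-3 substrates and 1-2 products uniformly (substrates and products
#' disjoint within a reaction), reversibility is Bernoulli(0.3), predicted
#' delta G0 is Normal(0, 10) kJ/mol, and pathways are contiguous blocks of
#' reactions. The result round-trips through [writeNetwork()] /
#' [readNetwork()] unchanged.
#'
#' @param nReactions,nGenes,nMetabolites,nPathways sizes (all >= 1;
#'   `nMetabolites >= 5` so substrate/product draws never exhaust the pool).
#' @param seed integer RNG seed; identical seeds give identical networks.
#' @param otherCompartmentFraction fraction of metabolites assigned to
#'   non-cytoplasmic compartments (`"m"`, `"e"`); default 0 keeps the whole
#'   network cytoplasmic, which is what the omics generator measures.
#' @return a [MetabolicNetwork-class].
#' @export
generateNetwork <- function(nReactions, nGenes, nMetabolites, nPathways,
                            seed, otherCompartmentFraction = 0) {
  if (nReactions < 1L || nGenes < 1L || nPathways < 1L)
    stop("all sizes must be >= 1")
  if (nMetabolites < 5L)
    stop("nMetabolites must be >= 5 (substrate/product pools)")
  withSeed(seed, {
    comp <- rep("c", nMetabolites)
    nOther <- round(otherCompartmentFraction * nMetabolites)
    if (nOther > 0L)
      comp[sample.int(nMetabolites, nOther)] <-
        sample(c("m", "e"), nOther, replace = TRUE)
    mets <- sprintf("m%04d[%s]", seq_len(nMetabolites), comp)
    genes <- sprintf("g%04d", seq_len(nGenes))
    rxn <- sprintf("R%04d", seq_len(nReactions))
    pathway <- sprintf("P%02d",
                       ceiling(seq_len(nReactions) * nPathways / nReactions))
    rows <- lapply(seq_len(nReactions), function(i) {
      gs <- sample(genes, sample(1:3, 1L))
      ss <- sample(mets, sample(1:3, 1L))
      ps <- sample(setdiff(mets, ss), sample(1:2, 1L))
      data.frame(reaction_id = rxn[i],
                 genes = paste(sort(gs), collapse = ";"),
                 substrates = paste(sort(ss), collapse = ";"),
                 products = paste(sort(ps), collapse = ";"),
                 reversible = rbinom(1L, 1L, 0.3),
                 delta_g0 = rnorm(1L, 0, 10),
                 pathway = pathway[i],
                 stringsAsFactors = FALSE)
    })
    networkFromTable(do.call(rbind, rows))
  })
}

# Pearson latent correlation giving a bivariate-normal population Spearman
# equal to rhoS (inverse of rho_S = (6/pi) asin(r/2)).
latentPearson <- function(rhoS) 2 * sin(pi * rhoS / 6)

#' Generate a two-condition omics cohort with planted couplings
#'
#' Couplings are planted as per-metabolite modules on the Gaussian copula
#' scale. A coupled metabolite *m* in condition *c* draws a latent factor
#' `u_m`; its latent level in the samples of *c* is
#' `sqrt(r) * u_m + sqrt(1 - r) * noise`, and every gene claimed by the
#' module follows `sign * sqrt(r) * u_m + sqrt(1 - r) * noise` in those
#' samples, with `r = 2 sin(pi * rho_target / 6)`, so the *population
#' Spearman* of each planted gene-metabolite pair equals `rho_target`
#' exactly (Spearman is invariant to the monotone exponentiation applied
#' afterwards). A gene belongs to at most one module per condition, so
#' couplings stay specific to network-connected pairs; the number of
#' plantable pairs is therefore bounded by the gene pool, and a request
#' beyond that bound plants as many pairs as the pool affords (with a
#' warning). Module claiming is greedy: hot-pathway pairs are claimed
#' first, then metabolites claim one still-free connected gene per pass in
#' round-robin until the pair budget `round(fraction * n_pairs)` is met,
#' balancing coverage across metabolites.
#'
#' Baseline expression of gene *g* is Normal(mu_g, sigma_g) with mu_g ~
#' U(4, 12), sigma_g ~ U(0.2, 1.5) (log-scale units); genes in planted
#' modules have sigma_g multiplied by `sqrt(varMultiplier)`, emulating the
#' elevated expression variance of coupling-associated genes. The planted
#' sign follows the pair's reaction role (product pairs couple positively,
#' substrate-only pairs negatively) with probability `roleSignProb`.
#'
#' @param network a [MetabolicNetwork-class].
#' @param nSamplesPerCondition samples per condition (default 50).
#' @param couplingFraction named fractions of connected pairs coupled per
#'   condition, e.g. `c(noncancerous = 0.1, cancer = 0.4)`.
#' @param strengthRange range of planted Spearman targets, within (0, 1];
#'   one strength is drawn per module (shared by its pairs).
#' @param noiseSd SD of the independent noise terms (1 keeps the planted
#'   Spearman at `rho_target`).
#' @param varMultiplier variance multiplier (>= 1) for coupled genes.
#' @param diffexpShift mean shift (in units of the gene's own SD) added to
#'   every coupled gene's expression in the cancer samples, emulating the
#'   observed association between coupling strength and differential
#'   expression; within-stratum correlations are unaffected. Default 1.
#' @param hotPathway optional pathway label (or vector of labels); pairs
#'   connected through reactions of these pathways are claimed first,
#'   localizing couplings there. Within any claiming step, pairs whose net
#'   role is unambiguous (production-only or consumption-only across their
#'   connecting reactions) are preferred, since mixed-role pairs have no
#'   clear coupling direction.
#' @param roleSignProb probability that a planted pair's sign follows its
#'   reaction role (product +, substrate -); default 0.9 emulates the
#'   observed *tendency* of products to couple positively without making
#'   the role flag a perfect label. 0.5 gives random signs.
#' @param couplingCompartment compartment(s) whose connected pairs are
#'   eligible for planting (default `"c"`, the measured cytoplasmic layer;
#'   `NULL` for all compartments). `couplingFraction` is a fraction of the
#'   eligible pairs.
#' @param hazardLinks optional data.frame (`metabolite_id`, `coef`) of
#'   planted log-hazard coefficients per SD of log metabolite, recorded in
#'   the truth for [generateClinical()].
#' @param erLink optional list (`metabolite_id`, `shift`) linking one
#'   metabolite to the ER-like binary label.
#' @param seed integer RNG seed.
#' @return list with `cohort` (a [GMCohort-class]) and `truth` (class
#'   `SyntheticTruth`: `coupledPairs` with per-pair condition, strength and
#'   sign, `hazardLinks`, `erLink`, `hotPathway`, `seed`).
#' @export
generateOmics <- function(network, nSamplesPerCondition = 50,
                          couplingFraction = c(noncancerous = 0.1,
                                               cancer = 0.4),
                          strengthRange = c(0.5, 0.9), noiseSd = 1,
                          varMultiplier = 2, diffexpShift = 1,
                          hotPathway = NULL,
                          roleSignProb = 0.9, couplingCompartment = "c",
                          hazardLinks = NULL, erLink = NULL, seed = 1) {
  stopifnot(all(couplingFraction >= 0 & couplingFraction <= 1),
            all(strengthRange > 0 & strengthRange <= 1),
            varMultiplier >= 1)
  conds <- c("noncancerous", "cancer")
  if (!all(conds %in% names(couplingFraction)))
    names(couplingFraction) <- conds
  pairs <- connectedGMPairs(network, compartment = couplingCompartment)
  nPairs <- nrow(pairs)
  wanted <- round(couplingFraction[conds] * nPairs)
  if (any(wanted > nPairs))
    stop("requested more coupled pairs than connected pairs")

  rx <- reactions(network)
  rm_ <- reactionMetaboliteLinks(network)
  geneIds <- networkGenes(network)$gene_id
  metIds <- networkMetabolites(network)$metabolite_id
  n <- nSamplesPerCondition
  condition <- rep(conds, each = n)
  samples <- sprintf("s%04d", seq_along(condition))

  # net role of each connected pair: the majority role over its connecting
  # links (production vs consumption balance), ties resolved to product.
  # Pairs carrying both roles have an ambiguous net coupling direction and
  # are claimed last.
  roleInfo <- lapply(seq_len(nPairs), function(i) {
    rxs <- pairs$reaction_ids[[i]]
    roles <- rm_$role[rm_$reaction_id %in% rxs &
                      rm_$metabolite_id == pairs$metabolite_id[i]]
    list(role = if (sum(roles == "product") >= sum(roles == "substrate"))
           "product" else "substrate",
         mixed = any(roles == "product") && any(roles == "substrate"))
  })
  pairRole <- vapply(roleInfo, `[[`, "", "role")
  pairMixed <- vapply(roleInfo, `[[`, TRUE, "mixed")
  hotEligible <- if (is.null(hotPathway)) rep(FALSE, nPairs) else
    vapply(pairs$reaction_ids, function(rxs)
      any(rx$pathway[match(rxs, rx$reaction_id)] %in% hotPathway), TRUE)
  pairsByMet <- split(seq_len(nPairs), pairs$metabolite_id)

  withSeed(seed, {
    mu <- runif(length(geneIds), 4, 12)
    sigma <- runif(length(geneIds), 0.2, 1.5)
    names(mu) <- names(sigma) <- geneIds

    # greedy module claiming for one condition. Hot-pathway pairs are
    # claimed first (localizing couplings); the remaining budget is spread
    # round-robin, one gene per metabolite per pass, so coverage is
    # balanced across metabolites. A gene serves at most one metabolite
    # per condition (the correlation-feasibility budget at rho near 0.7).
    pickModules <- function(budget) {
      if (budget == 0L) return(integer(0))
      freeGene <- setNames(rep(TRUE, length(geneIds)), geneIds)
      chosen <- integer(0)
      claim <- function(ix) {
        ok <- freeGene[pairs$gene_id[ix]]
        ix <- head(ix[ok], budget - length(chosen))
        if (length(ix)) {
          chosen <<- c(chosen, ix)
          freeGene[pairs$gene_id[ix]] <<- FALSE
        }
      }
      if (any(hotEligible)) {
        ix <- sample(which(hotEligible))
        claim(ix[order(pairMixed[ix])])   # unambiguous roles first
      }
      metsShuffled <- sample(names(pairsByMet))
      pairOrder <- lapply(pairsByMet, function(ix) {
        ix <- sample(ix)
        ix[order(pairMixed[ix])]
      })
      while (length(chosen) < budget) {
        before <- length(chosen)
        for (m in metsShuffled) {
          if (length(chosen) >= budget) break
          ix <- pairOrder[[m]]
          ix <- ix[!(ix %in% chosen) & freeGene[pairs$gene_id[ix]]]
          if (length(ix)) claim(ix[1L])
        }
        if (length(chosen) == before) break
      }
      if (length(chosen) < budget)
        warning(sprintf(
          "coupling budget %d exceeds the plantable pair bound; planted %d",
          budget, length(chosen)))
      chosen
    }
    sel <- lapply(setNames(conds, conds),
                  function(cd) pickModules(wanted[[cd]]))
    planted <- unique(unlist(sel))
    coupledPairs <- NULL
    moduleStrength <- setNames(
      runif(length(metIds), strengthRange[1], strengthRange[2]), metIds)
    if (length(planted)) {
      roleS <- ifelse(pairRole[planted] == "product", 1, -1)
      flip <- sample(c(1, -1), length(planted), replace = TRUE,
                     prob = c(roleSignProb, 1 - roleSignProb))
      sign_ <- roleS * flip
      condOf <- ifelse(planted %in% sel$noncancerous &
                       planted %in% sel$cancer, "both",
                ifelse(planted %in% sel$cancer, "cancer", "noncancerous"))
      coupledPairs <- data.frame(
        gene_id = pairs$gene_id[planted],
        metabolite_id = pairs$metabolite_id[planted],
        condition = condOf,
        strength = unname(moduleStrength[pairs$metabolite_id[planted]]),
        sign = sign_,
        stringsAsFactors = FALSE)
    }

    coupledGenes <- unique(coupledPairs$gene_id)
    sigma[coupledGenes] <- sigma[coupledGenes] * sqrt(varMultiplier)

    # latent gene scores: baseline noise, overwritten on module samples
    zExpr <- matrix(rnorm(length(geneIds) * length(samples)),
                    nrow = length(geneIds), ncol = length(samples),
                    dimnames = list(geneIds, samples))
    base <- runif(length(metIds), 1, 3); names(base) <- metIds
    metZ <- matrix(rnorm(length(metIds) * length(samples), sd = noiseSd),
                   nrow = length(metIds), ncol = length(samples),
                   dimnames = list(metIds, samples))

    if (!is.null(coupledPairs)) {
      for (m in unique(coupledPairs$metabolite_id)) {
        r <- latentPearson(moduleStrength[[m]])
        for (cd in conds) {
          mods <- coupledPairs[coupledPairs$metabolite_id == m &
                               coupledPairs$condition %in% c(cd, "both"), ,
                               drop = FALSE]
          if (nrow(mods) == 0L) next
          idx <- which(condition == cd)
          u <- rnorm(length(idx))
          metZ[m, idx] <- sqrt(r) * u +
            sqrt(1 - r) * rnorm(length(idx), sd = noiseSd)
          for (j in seq_len(nrow(mods)))
            zExpr[mods$gene_id[j], idx] <-
              mods$sign[j] * (sqrt(r) * u +
                              sqrt(1 - r) * rnorm(length(idx)))
        }
      }
    }
    expr <- mu + sigma * zExpr
    if (length(coupledGenes) && diffexpShift != 0)
      expr[coupledGenes, condition == "cancer"] <-
        expr[coupledGenes, condition == "cancer"] +
        diffexpShift * sigma[coupledGenes]
    metab <- exp(base + 0.5 * metZ)

    sd_ <- data.frame(condition = condition, survival_time = NA_real_,
                      event = NA, er_status = NA,
                      row.names = samples, stringsAsFactors = FALSE)
    cohort <- GMCohort(expr, metab, sd_)
    truth <- structure(list(coupledPairs = coupledPairs,
                            hazardLinks = hazardLinks, erLink = erLink,
                            hotPathway = hotPathway, seed = seed),
                       class = "SyntheticTruth")
    list(cohort = cohort, truth = truth)
  })
}

#' Fill clinical outcomes from planted hazard and ER links
#'
#' Survival times are drawn from an exponential proportional-hazards model:
#' `T ~ Exp(rate = baselineHazard * exp(sum coef_j * z_j))` where `z_j` is
#' the z-scored log level of the j-th hazard-linked metabolite. Censoring is
#' independent Uniform(0, tMax) (about 30-40% censored at the defaults).
#' The ER-like label is Bernoulli with logit `shift * z` of the ER-linked
#' metabolite (fair coin when no link is planted).
#'
#' @param cohort a [GMCohort-class].
#' @param truth a `SyntheticTruth` from [generateOmics()] (its
#'   `hazardLinks` / `erLink` drive the planting; `NULL` entries give a
#'   global null).
#' @param baselineHazard events per month at linear predictor 0
#'   (default 1/24: median survival about 17 months).
#' @param tMax upper bound of the uniform censoring time, months.
#' @param seed integer RNG seed.
#' @return the cohort with `survival_time`, `event`, `er_status` filled.
#' @export
generateClinical <- function(cohort, truth, baselineHazard = 1 / 24,
                             tMax = 60, seed = 1) {
  metab <- metaboliteMatrix(cohort)
  sdat <- sampleData(cohort)
  nS <- nrow(sdat)
  zOf <- function(m) {
    v <- log(metab[m, ])
    (v - mean(v)) / sd(v)
  }
  lp <- rep(0, nS)
  hl <- truth$hazardLinks
  if (!is.null(hl) && nrow(hl) > 0) for (i in seq_len(nrow(hl))) {
    if (!(hl$metabolite_id[i] %in% rownames(metab)))
      stop("hazard link references unknown metabolite: ", hl$metabolite_id[i])
    lp <- lp + hl$coef[i] * zOf(hl$metabolite_id[i])
  }
  withSeed(seed, {
    tEvent <- rexp(nS, rate = baselineHazard * exp(lp))
    tCens <- runif(nS, 0, tMax)
    sdat$survival_time <- pmin(tEvent, tCens)
    sdat$event <- tEvent <= tCens
    eta <- if (!is.null(truth$erLink))
      truth$erLink$shift * zOf(truth$erLink$metabolite_id) else rep(0, nS)
    sdat$er_status <- rbinom(nS, 1L, plogis(eta))
    GMCohort(expressionMatrix(cohort), metab, sdat)
  })
}

#' @rdname generateClinical
#' @param ... unused
#' @param x a `SyntheticTruth`
#' @export
print.SyntheticTruth <- function(x, ...) {
  cat("SyntheticTruth: ",
      if (is.null(x$coupledPairs)) 0 else nrow(x$coupledPairs),
      " planted couplings; hazard links: ",
      if (is.null(x$hazardLinks)) 0 else nrow(x$hazardLinks),
      "; ER link: ", if (is.null(x$erLink)) "none" else
        x$erLink$metabolite_id,
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- cohort / truth I/O ---------------------------------------------------

#' Write / read a cohort and its ground truth
#'
#' `writeCohort()` emits `expression.tsv` and `metabolites.tsv` (entity x
#' sample, tab-delimited with a leading ID column) plus `clinical.tsv`
#' (sample, condition, survival_time, event, er_status); `writeTruth()`
#' serializes a `SyntheticTruth` to JSON. The readers invert them.
#'
#' @param cohort a [GMCohort-class].
#' @param dir output directory (created if missing).
#' @return the directory (writers) or the reconstructed object (readers),
#'   invisibly for writers.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(M, path, idcol) {
    df <- data.frame(id = rownames(M), M, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1] <- idcol
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wm(expressionMatrix(cohort), file.path(dir, "expression.tsv"), "gene_id")
  wm(metaboliteMatrix(cohort), file.path(dir, "metabolites.tsv"),
     "metabolite_id")
  sdat <- sampleData(cohort)
  clin <- data.frame(sample_id = rownames(sdat), sdat,
                     stringsAsFactors = FALSE)
  write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  rm_ <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    M <- as.matrix(df[, -1, drop = FALSE])
    rownames(M) <- df[[1]]
    M
  }
  expr <- rm_(file.path(dir, "expression.tsv"))
  metab <- rm_(file.path(dir, "metabolites.tsv"))
  clin <- read.delim(file.path(dir, "clinical.tsv"),
                     stringsAsFactors = FALSE)
  rownames(clin) <- clin$sample_id
  clin$sample_id <- NULL
  GMCohort(expr, metab, clin)
}

#' @rdname writeCohort
#' @param truth a `SyntheticTruth`.
#' @param path JSON file path.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$coupledPairs)) x$coupledPairs <-
      as.data.frame(x$coupledPairs, stringsAsFactors = FALSE)
  if (!is.null(x$hazardLinks)) x$hazardLinks <-
      as.data.frame(x$hazardLinks, stringsAsFactors = FALSE)
  structure(x, class = "SyntheticTruth")
}
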