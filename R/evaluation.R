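# Design-quality evaluation: validity / uniqueness / novelty, syntax-error
# taxonomy, property profiles with Kolmogorov-Smirnov distances,
# rediscovery, scaffold clustering, and the prospective design-selection
# protocol.

#' Validity, uniqueness and novelty of generated designs
#'
#' valid = designs parseable as molecules; unique = distinct canonical
#' forms among the valid ones; novel = unique designs whose canonical form
#' is absent from the training set. All fractions use the total generated
#' count as denominator. Invalid designs are classified into the
#' branching/ring/bond/other error taxonomy.
#'
#' @param designs character vector of generated SMILES
#' @param training_set canonical training SMILES
#' @return an `evaluation_report` list: counts, fractions, `taxonomy`
#'   table, per-design `detail` data.frame
#' @export
validity_uniqueness_novelty <- function(designs, training_set = character()) {
  n <- length(designs)
  rec <- if (n) canonicalize_and_validate(designs) else
    data.frame(raw = character(), canonical = character(), valid = logical())
  valid <- rec$valid
  canon <- rec$canonical
  uniq <- valid & !duplicated(canon) & !is.na(canon)
  novel <- uniq & !(canon %in% training_set)
  tax <- c(branching = 0L, ring = 0L, bond = 0L, other = 0L)
  if (any(!valid)) {
    cls <- classify_invalid_smiles(designs[!valid])
    tb <- table(factor(cls, levels = names(tax)))
    tax[names(tb)] <- as.integer(tb)
  }
  structure(list(
    n_generated = n,
    n_valid = sum(valid), n_unique = sum(uniq), n_novel = sum(novel),
    frac_valid = if (n) sum(valid) / n else 0,
    frac_unique = if (n) sum(uniq) / n else 0,
    frac_novel = if (n) sum(novel) / n else 0,
    taxonomy = tax,
    detail = data.frame(smiles = designs, canonical = canon, valid = valid,
                        unique = uniq, novel = novel,
                        stringsAsFactors = FALSE)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("designs: %d | valid %d (%.1f%%) | unique %d (%.1f%%) | novel %d (%.1f%%)\n",
              x$n_generated, x$n_valid, 100 * x$frac_valid,
              x$n_unique, 100 * x$frac_unique, x$n_novel, 100 * x$frac_novel))
  cat("error taxonomy:", paste(names(x$taxonomy), x$taxonomy, sep = "=",
                               collapse = " "), "\n")
  invisible(x)
}

#' Classify invalid SMILES into an error taxonomy
#'
#' Categories, in precedence order:
#' \describe{
#'   \item{branching}{unbalanced parentheses}
#'   \item{ring}{unmatched ring-closure labels}
#'   \item{bond}{syntactically parseable but chemically impossible
#'     (valence / bond-order violation)}
#'   \item{other}{remaining parse failures}
#' }
#'
#' @param smiles character vector of *invalid* SMILES; passing a valid
#'   string is a contract violation and errors
#' @return character vector of category labels
#' @export
classify_invalid_smiles <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  # strip bracket-atom contents for the syntax checks
  stripped <- gsub("\\[[^]]*\\]", "A", smiles)
  for (i in seq_len(n)) {
    s <- stripped[i]
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    depth <- 0L; bad <- FALSE
    for (c0 in ch) {
      if (c0 == "(") depth <- depth + 1L
      else if (c0 == ")") { depth <- depth - 1L; if (depth < 0L) { bad <- TRUE; break } }
    }
    if (bad || depth != 0L) { out[i] <- "branching"; next }
    # ring labels: %nn pairs and bare digits
    lab <- character(0)
    j <- 1L; m <- length(ch)
    while (j <= m) {
      if (ch[j] == "%" && j + 2L <= m && grepl("[0-9]", ch[j + 1L]) &&
          grepl("[0-9]", ch[j + 2L])) {
        lab <- c(lab, paste0("%", ch[j + 1L], ch[j + 2L])); j <- j + 3L
      } else if (grepl("[0-9]", ch[j])) {
        lab <- c(lab, ch[j]); j <- j + 1L
      } else j <- j + 1L
    }
    if (length(lab) && any(table(lab) %% 2L == 1L)) { out[i] <- "ring"; next }
  }
  todo <- which(is.na(out))
  if (length(todo)) {
    info <- chem_sanitize_info(smiles[todo])
    if (any(info$parse_ok & info$sanitize_ok)) {
      stop("classify_invalid_smiles called on a valid SMILES string",
           call. = FALSE)
    }
    out[todo] <- ifelse(info$parse_ok & !info$sanitize_ok, "bond", "other")
  }
  out
}

# ---------------------------------------------------------------------------
# property profiles

#' Fragment-frequency scoring model
#'
#' Circular-fragment log-odds weights contrasting a positive against a
#' negative reference corpus, the mechanism behind natural-product-likeness
#' and fragment-based synthetic-accessibility estimates. Weights are
#' Laplace-smoothed log10 frequency ratios.
#'
#' @param positive,negative reference SMILES corpora
#' @param radius circular fragment radius (default 2)
#' @return a `fragment_score_model`
#' @export
fragment_score_model <- function(positive, negative, radius = 2L) {
  count_frags <- function(smiles) {
    lines <- chem_call("fragments", smiles, c("--radius", radius))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    tab <- new.env(parent = emptyenv())
    tot <- 0
    for (p in parts) {
      if (p[1] != "1") next
      ids <- strsplit(p[3] %||% "", " ", fixed = TRUE)[[1]]
      ids <- ids[nzchar(ids)]
      for (id in unique(ids)) {
        tab[[id]] <- (tab[[id]] %||% 0) + 1
      }
      tot <- tot + 1
    }
    list(tab = tab, n = tot)
  }
  pos <- count_frags(positive); neg <- count_frags(negative)
  all_ids <- union(ls(pos$tab), ls(neg$tab))
  w <- vapply(all_ids, function(id) {
    fp <- (pos$tab[[id]] %||% 0) + 1
    fn <- (neg$tab[[id]] %||% 0) + 1
    log10((fp / (pos$n + 1)) / (fn / (neg$n + 1)))
  }, numeric(1))
  structure(list(weights = stats::setNames(w, all_ids), radius = radius),
            class = "fragment_score_model")
}

#' Score molecules under a fragment-frequency model
#'
#' Mean weight of the molecule's distinct circular fragments under a
#' [fragment_score_model()]; unseen fragments contribute 0.
#'
#' @param smiles molecules to score
#' @param model a `fragment_score_model`
#' @return numeric scores (NA for unparseable molecules)
#' @export
fragment_scores <- function(smiles, model) {
  lines <- chem_call("fragments", smiles, c("--radius", model$radius))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  vapply(parts, function(p) {
    if (p[1] != "1") return(NA_real_)
    ids <- unique(strsplit(p[3] %||% "", " ", fixed = TRUE)[[1]])
    ids <- ids[nzchar(ids)]
    if (!length(ids)) return(0)
    w <- model$weights[ids]
    w[is.na(w)] <- 0
    mean(w)
  }, numeric(1))
}

#' Molecular property profile
#'
#' Per-molecule descriptors used to compare designs with training data:
#' octanol-water partition coefficient (clogP), drug-likeness (QED), Bertz
#' complexity, a synthetic-accessibility estimate, natural-product
#' likeness, sp3-carbon count, aliphatic-ring count, spiro-atom count,
#' molecular weight (Da), largest fused-ring-system size (rings) and
#' heavy-atom count.
#'
#' NP-likeness requires a [fragment_score_model()] contrasting a
#' natural-product-like against a synthetic reference; the
#' synthetic-accessibility estimate combines a fragment-commonness term
#' (when `sa_model` is given) with structural-complexity penalties (ring
#' complexity, stereo centers, spiro atoms, macrocycles, size). Without
#' reference models those two columns are NA.
#'
#' @param smiles valid molecules
#' @param np_model,sa_model optional [fragment_score_model()]s
#' @return data.frame of descriptors, one row per molecule; molecules
#'   failing descriptor computation carry NA rows
#' @export
property_profile <- function(smiles, np_model = NULL, sa_model = NULL) {
  lines <- chem_call("descript", smiles)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  ok <- df$ok == 1
  out <- data.frame(
    smiles = smiles,
    logp = df$logp, qed = df$qed, bertz = df$bertz,
    sa_estimate = NA_real_, np_likeness = NA_real_,
    n_sp3_carbons = df$n_sp3_c,
    n_aliphatic_rings = df$n_aliphatic_rings,
    n_spiro_atoms = df$n_spiro,
    molecular_weight = df$mw,
    fused_ring_size = df$fused_ring_size,
    n_heavy_atoms = df$n_heavy,
    stringsAsFactors = FALSE
  )
  if (!is.null(np_model)) {
    out$np_likeness <- fragment_scores(smiles, np_model)
  }
  if (!is.null(sa_model)) {
    frag <- fragment_scores(smiles, sa_model)
    # complexity penalties on top of fragment commonness
    pen <- log10(df$n_stereo + 1) + 2 * log10(df$n_spiro + 1) +
      ifelse(df$n_macro > 0, log10(2), 0) +
      (df$n_heavy^1.005 - df$n_heavy)
    raw <- -4 * frag + pen
    # map to the conventional 1 (easy) .. 10 (hard) range
    out$sa_estimate <- pmin(10, pmax(1, 3 + raw))
  }
  out[!ok, -1L] <- NA
  out
}

#' Summary of a property profile (mean and standard deviation)
#'
#' @param profile data.frame from [property_profile()]
#' @return data.frame with `descriptor`, `mean`, `sd`
#' @export
property_summary <- function(profile) {
  num <- profile[vapply(profile, is.numeric, logical(1))]
  data.frame(descriptor = names(num),
             mean = vapply(num, function(v) mean(v, na.rm = TRUE), numeric(1)),
             sd = vapply(num, function(v) stats::sd(v, na.rm = TRUE), numeric(1)),
             row.names = NULL)
}

#' Two-sample Kolmogorov-Smirnov distance, in percent
#'
#' Supremum difference between the two empirical cumulative distribution
#' functions, times 100. Symmetric, in [0, 100]; 0 iff the ECDFs coincide
#' at every sample point; 100 for disjoint supports.
#'
#' @param a,b non-empty numeric samples
#' @return distance in percent
#' @export
ks_distance <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("ks_distance needs non-empty samples")
  pts <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(pts); Fb <- stats::ecdf(b)(pts)
  100 * max(abs(Fa - Fb))
}

#' Property table with KS distances to train and test sets
#'
#' For each descriptor: mean and sd over the designs plus the KS distance
#' of the design distribution to the training and test distributions.
#'
#' @param designs,train,test property data.frames from [property_profile()]
#' @return data.frame with one row per descriptor
#' @export
property_ks_table <- function(designs, train, test) {
  cols <- setdiff(names(designs)[vapply(designs, is.numeric, logical(1))],
                  "smiles")
  rows <- lapply(cols, function(cn) {
    dv <- designs[[cn]]; tv <- train[[cn]]; sv <- test[[cn]]
    if (all(is.na(dv))) {
      return(data.frame(descriptor = cn, mean = NA, sd = NA,
                        ks_train = NA, ks_test = NA))
    }
    data.frame(descriptor = cn,
               mean = mean(dv, na.rm = TRUE), sd = stats::sd(dv, na.rm = TRUE),
               ks_train = ks_distance(dv, tv), ks_test = ks_distance(dv, sv))
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# rediscovery and scaffold clustering

#' Rediscovery rate of held-out actives
#'
#' relaxed mode: fraction of held-out actives with at least one design of
#' Tanimoto similarity strictly above `threshold` (extended-connectivity
#' fingerprints, radius 3, 2048 bits). exact mode: fraction with an
#' identical canonical structure among the designs.
#'
#' @param designs valid design SMILES (canonical or canonicalizable)
#' @param actives held-out active SMILES (canonical)
#' @param threshold similarity threshold for relaxed mode (default 0.6)
#' @param mode `"relaxed"` or `"exact"`
#' @return rediscovery rate in [0, 1]
#' @export
rediscovery_rate <- function(designs, actives, threshold = 0.6,
                             mode = c("relaxed", "exact")) {
  mode <- match.arg(mode)
  if (!length(actives)) stop("empty set of held-out actives")
  if (!length(designs)) return(0)
  rec <- canonicalize_and_validate(designs)
  dcan <- unique(rec$canonical[rec$valid])
  if (!length(dcan)) return(0)
  if (mode == "exact") {
    return(mean(actives %in% dcan))
  }
  fa <- morgan_fingerprints(actives); fd <- morgan_fingerprints(dcan)
  sim <- tanimoto_matrix(fa, fd)
  mean(apply(sim, 1L, max) > threshold)
}

#' Scaffold cluster count of a design set
#'
#' Extracts Bemis-Murcko scaffolds, fingerprints them
#' (extended-connectivity, radius 3, 2048 bits) and groups scaffolds whose
#' Tanimoto similarity is strictly above the threshold by single-linkage
#' hierarchical clustering (equivalently: connected components of the
#' similarity threshold graph). Acyclic molecules have an empty scaffold
#' and are collected in a dedicated no-scaffold cluster.
#'
#' @param designs valid, unique, novel design SMILES
#' @param threshold Tanimoto similarity threshold (default 0.6)
#' @return list with `n_clusters`, per-design `labels`, `scaffolds`
#' @export
scaffold_cluster_count <- function(designs, threshold = 0.6) {
  sc <- murcko_scaffolds(designs)
  no_scaf <- is.na(sc) | sc == ""
  labels <- integer(length(designs))
  uniq <- unique(sc[!no_scaf])
  n_clusters <- 0L
  if (length(uniq) == 1L) {
    n_clusters <- 1L
    labels[!no_scaf] <- 1L
  } else if (length(uniq) > 1L) {
    fp <- morgan_fingerprints(uniq)
    sim <- tanimoto_matrix(fp)
    d <- stats::as.dist(1 - sim)
    hc <- stats::hclust(d, method = "single")
    # merge while similarity > threshold, i.e. distance < 1 - threshold
    cl <- stats::cutree(hc, h = (1 - threshold) - 1e-9)
    n_clusters <- max(cl)
    labels[!no_scaf] <- cl[match(sc[!no_scaf], uniq)]
  }
  if (any(no_scaf)) {
    n_clusters <- n_clusters + 1L
    labels[no_scaf] <- n_clusters
    s4clm_log("INFO", "evaluate",
              sprintf("%d acyclic design(s) assigned to the no-scaffold cluster",
                      sum(no_scaf)))
  }
  list(n_clusters = n_clusters, labels = labels, scaffolds = sc,
       threshold = threshold, linkage = "single")
}

# ---------------------------------------------------------------------------
# prospective selection protocol

#' Select prospective designs for experimental follow-up
#'
#' The campaign-level shortlist protocol: keep unique and novel designs,
#' rank them by fine-tuning log-likelihood and keep the `top_n`; split
#' those into high- and low-similarity groups by the Tanimoto similarity of
#' their Bemis-Murcko scaffold fingerprints to the fine-tuning set
#' (threshold `sim_threshold`, strict); within each group, designs are
#' grouped by their most-similar fine-tuning molecule and the highest
#' bias-corrected scorer per group is picked; each shortlist is returned
#' ranked by score.
#'
#' @param designs data.frame with columns `smiles`, `ll_ft` (fine-tuning
#'   log-likelihood) and `score` (bias-corrected)
#' @param finetune_set fine-tuning SMILES (canonical)
#' @param top_n designs retained after likelihood ranking (default 5000)
#' @param sim_threshold scaffold-similarity split threshold (default 0.6)
#' @param training_set set against which novelty is assessed (defaults to
#'   the fine-tuning set)
#' @return list with data.frames `high` and `low` (columns of `designs`
#'   plus `nearest_train`, `scaffold_similarity`), each sorted by `score`
#' @export
select_prospective_designs <- function(designs, finetune_set, top_n = 5000L,
                                       sim_threshold = 0.6,
                                       training_set = finetune_set) {
  stopifnot(all(c("smiles", "ll_ft", "score") %in% names(designs)))
  rec <- canonicalize_and_validate(designs$smiles)
  designs$canonical <- rec$canonical
  train_rec <- canonicalize_and_validate(training_set)
  train_canon <- train_rec$canonical[train_rec$valid]
  keep <- rec$valid & !duplicated(rec$canonical) &
    !(rec$canonical %in% train_canon)
  designs <- designs[keep, , drop = FALSE]
  if (nrow(designs) == 0L) stop("no unique novel designs to select from")
  designs <- designs[order(-designs$ll_ft), , drop = FALSE]
  if (nrow(designs) < top_n) {
    warning(sprintf("only %d candidates available (top_n = %d); keeping all",
                    nrow(designs), top_n))
  } else {
    designs <- designs[seq_len(top_n), , drop = FALSE]
  }
  scaf_d <- murcko_scaffolds(designs$canonical)
  scaf_t <- murcko_scaffolds(finetune_set)
  fp_d <- morgan_fingerprints(ifelse(is.na(scaf_d), "", scaf_d))
  fp_t <- morgan_fingerprints(ifelse(is.na(scaf_t), "", scaf_t))
  sim <- tanimoto_matrix(fp_d, fp_t)
  sim[!is.finite(sim)] <- 0
  designs$scaffold_similarity <- apply(sim, 1L, max)
  designs$nearest_train <- finetune_set[apply(sim, 1L, which.max)]
  pick <- function(df) {
    if (!nrow(df)) return(df)
    sp <- split(df, df$nearest_train)
    best <- do.call(rbind, lapply(sp, function(g) g[which.max(g$score), ]))
    best <- best[order(-best$score), , drop = FALSE]
    rownames(best) <- NULL
    best
  }
  list(high = pick(designs[designs$scaffold_similarity > sim_threshold, ,
                           drop = FALSE]),
       low = pick(designs[designs$scaffold_similarity <= sim_threshold, ,
                          drop = FALSE]))
}
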