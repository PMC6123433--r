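## Model interrogation: digital staining, ranked patch groups with
## intra-patch moment statistics, a logistic-regression baseline on
## those moments, and ROC/AUC with bootstrap confidence intervals.

#' Digital stain overlay
#'
#' Upsamples the heatmap's per-location probabilities to the RGB image
#' grid (nearest neighbour) and alpha-blends red into every pixel whose
#' predicted ER-negative probability strictly exceeds the threshold;
#' pixels at or below the threshold are untouched.
#'
#' @param rgb numeric array `H x W x 3` in `[0, 255]` at the source
#'   resolution.
#' @param heatmap an [ERHeatmap-class] from [predictHeatmap()].
#' @param threshold probability cut (strict `>`; default 0.5).
#' @param alpha blend weight of the red overlay.
#' @return numeric array `H x W x 3`.
#' @export
digitalStain <- function(rgb, heatmap, threshold = 0.5, alpha = 0.35) {
    d <- dim(rgb)
    if (length(d) != 3L || d[3L] != 3L)
        stop("rgb must be an H x W x 3 array", call. = FALSE)
    pm <- heatmap@prob
    if (!nrow(pm) || !ncol(pm))
        stop("heatmap has no spatial locations", call. = FALSE)
    ri <- pmin(pmax(ceiling(seq_len(d[1L]) / d[1L] * nrow(pm)), 1L), nrow(pm))
    ci <- pmin(pmax(ceiling(seq_len(d[2L]) / d[2L] * ncol(pm)), 1L), ncol(pm))
    up <- pm[ri, ci, drop = FALSE]
    if (!identical(dim(up), d[1:2]))
        stop("heatmap could not be upsampled to the image grid",
             call. = FALSE)
    sel <- up > threshold
    out <- rgb
    red <- c(255, 0, 0)
    for (ch in 1:3) {
        m <- out[, , ch]
        m[sel] <- (1 - alpha) * m[sel] + alpha * red[ch]
        out[, , ch] <- m
    }
    out
}

#' Rank patches by score and split into equal groups
#'
#' Sorts the scores ascending (ER-positive to ER-negative; ties keep
#' input order) and assigns the first `floor(n/nGroups)` to group 1,
#' the next to group 2, and so on; the remainder (the highest-score
#' tail) is dropped (`NA`). Higher group index = more ER-negative.
#'
#' @param scores numeric vector of patch scores.
#' @param nGroups number of groups (default 15).
#' @return integer vector of group indices aligned with `scores`
#'   (`NA` = dropped), with attribute `groupSize`.
#' @examples
#' g <- rankAndGroup(runif(11161), 15)
#' table(g)        # 744 per group, 1 dropped
#' @export
rankAndGroup <- function(scores, nGroups = 15L) {
    n <- length(scores)
    if (nGroups < 1L) stop("nGroups must be >= 1", call. = FALSE)
    if (n < nGroups) stop("fewer scores than groups", call. = FALSE)
    gs <- as.integer(n %/% nGroups)
    ord <- order(scores)               # stable: ties keep insertion order
    grp <- rep(NA_integer_, n)
    grp[ord[seq_len(gs * nGroups)]] <- rep(seq_len(nGroups), each = gs)
    attr(grp, "groupSize") <- gs
    grp
}

.shapeFeatureNames <- c("major", "minor", "ratio", "area", "perimeter",
                        "circularity")

#' Intra-patch moment statistics
#'
#' Recovers the nuclei of a patch from its nonzero pixels and returns
#' the intra-patch mean and population variance (divide by n) of each
#' of the six shape features, plus the nucleus count. Empty patches
#' are flagged (`empty = TRUE`, statistics `NA`).
#'
#' @param patch a [FeaturePatch-class] (or bare `P x P x 12` array).
#' @return one-row data.frame: `n`, `empty`,
#'   `mean_<feature>` and `var_<feature>` for the six shape features.
#' @export
patchStats <- function(patch) {
    arr <- if (is(patch, "FeaturePatch")) patch@data else patch
    occ <- .occupiedMask(arr)
    n <- sum(occ)
    out <- data.frame(n = n, empty = n == 0L)
    for (i in seq_along(.shapeFeatureNames)) {
        v <- arr[, , i][occ]
        out[[paste0("mean_", .shapeFeatureNames[i])]] <-
            if (n) mean(v) else NA_real_
        out[[paste0("var_", .shapeFeatureNames[i])]] <-
            if (n) mean((v - mean(v))^2) else NA_real_
    }
    out
}

#' Statistics table for a list of patches
#'
#' @param patches list of [FeaturePatch-class].
#' @param scores optional per-patch scores to carry along.
#' @param group optional group indices from [rankAndGroup()].
#' @return data.frame with one row per patch.
#' @export
patchStatsTable <- function(patches, scores = NULL, group = NULL) {
    tab <- do.call(rbind, lapply(patches, patchStats))
    if (!is.null(scores)) tab$score <- scores
    if (!is.null(group)) tab$group <- group
    tab
}

#' Per-group summaries of intra-patch statistics
#'
#' Averages the intra-patch means and intra-patch variances within
#' each group (inter-patch mean) and reports standard errors
#' (`sd/sqrt(group size)`). Empty patches are excluded; empty groups
#' raise an error.
#'
#' @param stats data.frame from [patchStatsTable()] with a `group`
#'   column.
#' @return data.frame with one row per group and feature:
#'   `group, feature, meanOfMeans, seOfMeans, meanOfVars, seOfVars, n`.
#' @export
groupSummary <- function(stats) {
    if (!"group" %in% names(stats))
        stop("stats must have a 'group' column", call. = FALSE)
    stats <- stats[!is.na(stats$group) & !stats$empty, , drop = FALSE]
    groups <- sort(unique(stats$group))
    if (!length(groups)) stop("no non-empty patches in any group",
                              call. = FALSE)
    rows <- list()
    for (g in groups) {
        sub <- stats[stats$group == g, , drop = FALSE]
        if (!nrow(sub)) stop("empty group: ", g, call. = FALSE)
        for (f in .shapeFeatureNames) {
            mu <- sub[[paste0("mean_", f)]]
            vv <- sub[[paste0("var_", f)]]
            rows[[length(rows) + 1L]] <- data.frame(
                group = g, feature = f,
                meanOfMeans = mean(mu),
                seOfMeans = sd(mu) / sqrt(length(mu)),
                meanOfVars = mean(vv),
                seOfVars = sd(vv) / sqrt(length(vv)),
                n = nrow(sub))
        }
    }
    out <- do.call(rbind, rows)
    out$seOfMeans[is.na(out$seOfMeans)] <- 0
    out$seOfVars[is.na(out$seOfVars)] <- 0
    out
}

#' Logistic-regression baseline on intra-patch moments
#'
#' Fits an (unregularised, maximum-likelihood) logistic regression of
#' the patch label on the 12 predictors -- the intra-patch means and
#' variances of the six shape features -- standardised on the training
#' sample. Empty patches are excluded.
#'
#' @param patches list of [FeaturePatch-class] (e.g. 5000 randomly
#'   sampled training patches), or `NULL` when `stats` is supplied.
#' @param labels 0/1 vector aligned with the patches (defaults to the
#'   patch labels).
#' @param ridge optional L2 penalty; 0 = plain ML fit.
#' @param stats optional precomputed [patchStatsTable()] (memory-light
#'   alternative to holding all patches at once); must align with
#'   `labels`.
#' @return object of class `nucleoBaseline` (list with the glm fit and
#'   the feature scaler).
#' @export
logisticBaselineTrain <- function(patches, labels = NULL, ridge = 0,
                                  stats = NULL) {
    if (is.null(labels)) {
        if (is.null(patches))
            stop("labels are required when training from a stats table",
                 call. = FALSE)
        labels <- vapply(patches, function(p) as.numeric(p@label), 0)
    }
    tab <- if (is.null(stats)) patchStatsTable(patches) else stats
    keep <- !tab$empty
    if (!any(keep)) stop("no non-empty patches", call. = FALSE)
    labels <- as.numeric(labels)[keep]
    if (length(unique(labels)) < 2L)
        stop("training patches contain a single class", call. = FALSE)
    X <- as.matrix(tab[keep, c(paste0("mean_", .shapeFeatureNames),
                               paste0("var_", .shapeFeatureNames))])
    mu <- colMeans(X)
    sdv <- apply(X, 2L, sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Xs <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
    if (ridge > 0) {
        if (!requireNamespace("glmnet", quietly = TRUE))
            stop("the L2 option requires the glmnet package", call. = FALSE)
        fit <- glmnet::glmnet(Xs, labels, family = "binomial", alpha = 0,
                              lambda = ridge)
        return(structure(list(fit = fit, center = mu, scale = sdv,
                              features = colnames(X), engine = "glmnet"),
                         class = "nucleoBaseline"))
    }
    df <- as.data.frame(Xs)
    df$y <- labels
    fit <- suppressWarnings(
        stats::glm(y ~ ., data = df, family = stats::binomial(),
                   control = stats::glm.control(maxit = 100)))
    structure(list(fit = fit, center = mu, scale = sdv,
                   features = colnames(X), engine = "glm"),
              class = "nucleoBaseline")
}

#' Score a feature image with the logistic baseline
#'
#' Tiles the image into equally-spaced non-overlapping patches,
#' predicts the per-patch probability from the intra-patch moments and
#' averages over the non-empty patches.
#'
#' @param baseline a fitted `nucleoBaseline`.
#' @param img a [SparseFeatureImage-class].
#' @param patchSize tiling patch side in pixels (default 64).
#' @return image score in `[0, 1]`, or `NA` (with attribute
#'   `undefined = TRUE` and a warning) if every patch is empty.
#' @export
logisticBaselineScore <- function(baseline, img, patchSize = 64L) {
    stopifnot(inherits(baseline, "nucleoBaseline"))
    patches <- tilePatches(img, size = patchSize)
    if (!length(patches)) {
        warning("image has no complete tile; score undefined")
        out <- NA_real_; attr(out, "undefined") <- TRUE
        return(out)
    }
    tab <- patchStatsTable(patches)
    keep <- !tab$empty
    if (!any(keep)) {
        warning("image has no non-empty patch; score undefined")
        out <- NA_real_; attr(out, "undefined") <- TRUE
        return(out)
    }
    X <- as.matrix(tab[keep, baseline$features])
    Xs <- sweep(sweep(X, 2L, baseline$center), 2L, baseline$scale, "/")
    p <- if (identical(baseline$engine, "glmnet"))
        as.numeric(stats::predict(baseline$fit, newx = Xs,
                                  type = "response"))
    else
        stats::predict(baseline$fit, newdata = as.data.frame(Xs),
                       type = "response")
    mean(p)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Rank-based AUC: the probability that a random positive scores above
#' a random negative, ties counting one half.
#'
#' @param scores numeric scores (higher = more positive-class
#'   evidence).
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present", call. = FALSE)
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap confidence interval for the AUC
#'
#' Stratified percentile bootstrap: positives and negatives are
#' resampled separately, preserving class sizes.
#'
#' @inheritParams rocAuc
#' @param level confidence level.
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed.
#' @return numeric `c(low, high)`.
#' @export
aucCI <- function(scores, labels, level = 0.95, nBoot = 2000L, seed = 1L) {
    labels <- as.integer(labels)
    i1 <- which(labels == 1L); i0 <- which(labels == 0L)
    if (length(i1) < 2L || length(i0) < 2L)
        stop("each class needs at least 2 members", call. = FALSE)
    .withSeed(seed, {
        stat <- vapply(seq_len(nBoot), function(b) {
            j1 <- sample(i1, replace = TRUE)
            j0 <- sample(i0, replace = TRUE)
            rocAuc(c(scores[j1], scores[j0]),
                   c(rep(1L, length(j1)), rep(0L, length(j0))))
        }, numeric(1))
        unname(quantile(stat, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7))
    })
}
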