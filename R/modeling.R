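#' Specify a per-event classifier
#'
#' Fixes the algorithm, its (default) hyperparameters, the train/test
#' fraction and the seed for a per-event binary classification run.
#' Gradient boosting is the default algorithm; the others plug into the
#' identical evaluation contract.
#'
#' @param algorithm one of `"gradient_boosting"` (default),
#'   `"logistic_regression"`, `"random_forest"`, `"knn"`,
#'   `"linear_svm"`, `"lda"`.
#' @param cvFolds folds used when an algorithm tunes a hyperparameter
#'   internally (default 10; the fixed-default algorithms do not tune).
#' @param trainFrac fraction of samples used for training (default
#'   0.75).
#' @param seed base RNG seed for splitting and stochastic learners.
#' @param hyperparameters named list overriding algorithm defaults.
#'   Gradient boosting defaults: `nrounds = 100`, `max_depth = 3`,
#'   `eta = 0.1`, `subsample = 1`.
#' @return A `ModelSpec` list.
#' @export
modelSpec <- function(algorithm = c("gradient_boosting",
                                    "logistic_regression", "random_forest",
                                    "knn", "linear_svm", "lda"),
                      cvFolds = 10L, trainFrac = 0.75, seed = 1L,
                      hyperparameters = list()) {
    algorithm <- match.arg(algorithm)
    if (!is.numeric(trainFrac) || trainFrac <= 0 || trainFrac >= 1)
        stop("'trainFrac' must be in (0, 1)")
    if (cvFolds < 2) stop("'cvFolds' must be >= 2")
    defaults <- switch(algorithm,
        gradient_boosting = list(nrounds = 100L, max_depth = 3L,
                                 eta = 0.1, subsample = 1),
        logistic_regression = list(lambda = 1e-3),
        random_forest = list(num.trees = 100L),
        knn = list(k = 5L),
        linear_svm = list(cost = 1),
        lda = list())
    hp <- utils::modifyList(defaults, hyperparameters)
    structure(list(algorithm = algorithm, cvFolds = as.integer(cvFolds),
                   trainFrac = trainFrac, seed = as.integer(seed),
                   hyperparameters = hp),
              class = "ModelSpec")
}

.as01 <- function(labels) {
    if (is.logical(labels)) return(as.integer(labels))
    if (is.factor(labels)) labels <- as.character(labels)
    u <- sort(unique(labels))
    if (is.numeric(labels) && all(u %in% c(0, 1)))
        return(as.integer(labels))
    if (length(u) != 2L)
        stop("labels must be binary (got ", length(u), " classes)")
    as.integer(labels == u[2])
}

#' Stratified train/test split
#'
#' Splits sample indices into train and test partitions, stratified by
#' class so that the class balance is preserved within one sample in
#' each partition and neither partition is single-class. Deterministic
#' given the seed.
#'
#' @param labels binary labels (one per sample).
#' @param trainFrac training fraction (default 0.75).
#' @param seed RNG seed.
#' @return `list(train = <indices>, test = <indices>)`.
#' @export
splitData <- function(labels, trainFrac = 0.75, seed = 1L) {
    y <- .as01(labels)
    tab <- table(y)
    if (length(tab) < 2L)
        stop("both classes must be present")
    if (any(tab < 2L))
        stop("each class needs at least 2 members to stratify")
    withSeed(seed, {
        nTrain <- round(trainFrac * length(y))
        exact <- trainFrac * c(sum(y == 0), sum(y == 1))
        nTr <- floor(exact)
        ## largest-remainder allocation of the leftover slots
        left <- nTrain - sum(nTr)
        if (left > 0) {
            give <- order(-(exact - nTr))[seq_len(left)]
            nTr[give] <- nTr[give] + 1L
        }
        train <- integer(0)
        for (cls in c(0L, 1L)) {
            idx <- which(y == cls)
            k <- min(max(nTr[cls + 1L], 1L), length(idx) - 1L)
            train <- c(train, sample(idx, k))
        }
        train <- sort(train)
        list(train = train, test = setdiff(seq_along(y), train))
    })
}

.fitPredict <- function(algorithm, hp, Xtr, ytr, Xte, seed) {
    switch(algorithm,
        gradient_boosting = {
            fit <- withSeed(seed, xgboost::xgb.train(
                params = list(objective = "binary:logistic",
                              max_depth = hp$max_depth, eta = hp$eta,
                              subsample = hp$subsample, nthread = 1,
                              seed = seed),
                data = xgboost::xgb.DMatrix(Xtr, label = ytr,
                                            nthread = 1),
                nrounds = hp$nrounds, verbose = 0))
            predict(fit, xgboost::xgb.DMatrix(Xte, nthread = 1))
        },
        logistic_regression = {
            ## ridge-regularized logistic regression (p can exceed n)
            df <- data.frame(y = ytr, Xtr, check.names = FALSE)
            if (ncol(Xtr) < nrow(Xtr) / 2) {
                fit <- suppressWarnings(glm(y ~ ., data = df,
                                            family = binomial()))
                as.numeric(predict(fit,
                    data.frame(Xte, check.names = FALSE),
                    type = "response"))
            } else {
                if (!requireNamespace("glmnet", quietly = TRUE))
                    stop("glmnet is required for high-dimensional ",
                         "logistic regression")
                fit <- glmnet::glmnet(Xtr, ytr, family = "binomial",
                                      alpha = 0, lambda = hp$lambda)
                as.numeric(predict(fit, Xte, type = "response"))
            }
        },
        random_forest = {
            if (!requireNamespace("ranger", quietly = TRUE))
                stop("ranger is required for random_forest")
            fit <- ranger::ranger(x = Xtr, y = factor(ytr, c(0, 1)),
                                  probability = TRUE,
                                  num.trees = hp$num.trees,
                                  num.threads = 1, seed = seed)
            predict(fit, Xte, num.threads = 1)$predictions[, "1"]
        },
        knn = {
            if (!requireNamespace("class", quietly = TRUE))
                stop("the 'class' package is required for knn")
            pr <- withSeed(seed, class::knn(Xtr, Xte,
                                            cl = factor(ytr, c(0, 1)),
                                            k = hp$k, prob = TRUE))
            p <- attr(pr, "prob")
            ifelse(pr == "1", p, 1 - p)
        },
        linear_svm = {
            if (!requireNamespace("e1071", quietly = TRUE))
                stop("e1071 is required for linear_svm")
            fit <- withSeed(seed, e1071::svm(Xtr, factor(ytr, c(0, 1)),
                                             kernel = "linear",
                                             cost = hp$cost,
                                             probability = TRUE))
            pr <- predict(fit, Xte, probability = TRUE)
            attr(pr, "probabilities")[, "1"]
        },
        lda = {
            if (!requireNamespace("MASS", quietly = TRUE))
                stop("MASS is required for lda")
            fit <- suppressWarnings(MASS::lda(Xtr, grouping = ytr))
            as.numeric(predict(fit, Xte)$posterior[, "1"])
        },
        stop("unknown algorithm: ", algorithm))
}

#' Train and score a per-event classifier
#'
#' Fits the specified classifier on a stratified training partition and
#' scores the held-out test partition; performance is summarized as the
#' test-set AUROC ([auroc()]). Scores are predicted positive-class
#' probabilities.
#'
#' @param features variable x sample numeric matrix (genes, regulon
#'   activities or cluster aggregates).
#' @param labels binary event labels, one per sample (column).
#' @param spec a [modelSpec()].
#' @param split optional precomputed `list(train, test)` of sample
#'   indices (defaults to [splitData()] with the spec's seed).
#' @param eventId optional event identifier carried into the result.
#' @return A `ModelResult` list: `eventId`, `algorithm`, `scores`,
#'   `labels` (test), `auroc`, `nTrain`, `nTest`, `seed`.
#' @export
trainEventModel <- function(features, labels, spec = modelSpec(),
                            split = NULL, eventId = NULL) {
    m <- exprValues(features)
    if (any(!is.finite(m)))
        stop("non-finite feature values")
    y <- .as01(labels)
    if (length(y) != ncol(m))
        stop("labels must align with feature columns")
    if (is.null(split))
        split <- splitData(y, spec$trainFrac, spec$seed)
    ytr <- y[split$train]
    yte <- y[split$test]
    if (length(unique(ytr)) < 2L)
        stop("single-class training partition")
    if (length(unique(yte)) < 2L)
        stop("single-class test partition")
    X <- t(m)
    scores <- .fitPredict(spec$algorithm, spec$hyperparameters,
                          X[split$train, , drop = FALSE], ytr,
                          X[split$test, , drop = FALSE], spec$seed)
    structure(list(eventId = eventId, algorithm = spec$algorithm,
                   scores = as.numeric(scores), labels = yte,
                   auroc = auroc(scores, yte),
                   nTrain = length(ytr), nTest = length(yte),
                   seed = spec$seed),
              class = "ModelResult")
}

#' Repeated train/test evaluation
#'
#' Runs [trainEventModel()] over `reps` independent stratified splits
#' (seed schedule [seedSchedule()]`(spec$seed, 1, rep)`) and collects
#' the test-set AUROC distribution. Degenerate repetitions (e.g. a
#' split that cannot be stratified) are skipped and counted, not
#' imputed.
#'
#' @param features,labels,spec as in [trainEventModel()].
#' @param reps number of repetitions (default 100).
#' @param eventId optional event identifier.
#' @return An `AurocDistribution` list: `aurocs` (length `reps`, `NA`
#'   for failed reps), `mean`, `sd` (0 when a single value), `n`,
#'   `nFailed`, `eventId`, `algorithm`.
#' @export
repeatedEvaluation <- function(features, labels, spec = modelSpec(),
                               reps = 100L, eventId = NULL) {
    aurocs <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
        s <- spec
        s$seed <- seedSchedule(spec$seed, 1L, r)
        res <- tryCatch(trainEventModel(features, labels, s,
                                        eventId = eventId),
                        error = function(e) NULL)
        if (!is.null(res)) aurocs[r] <- res$auroc
    }
    ok <- !is.na(aurocs)
    if (!any(ok)) stop("all repetitions failed")
    structure(list(aurocs = aurocs, mean = mean(aurocs[ok]),
                   sd = if (sum(ok) > 1) sd(aurocs[ok]) else 0,
                   n = sum(ok), nFailed = sum(!ok), eventId = eventId,
                   algorithm = spec$algorithm),
              class = "AurocDistribution")
}

#' Bootstrap evaluation against a fixed test partition
#'
#' Technical-robustness variant of [repeatedEvaluation()]: one
#' stratified split fixes the test partition, then each bootstrap
#' resamples the training samples with replacement, refits, and scores
#' the fixed test set.
#'
#' @param features,labels,spec as in [trainEventModel()].
#' @param nBoot number of bootstrap refits (default 100).
#' @param eventId optional event identifier.
#' @return An `AurocDistribution` (see [repeatedEvaluation()]).
#' @export
bootstrapEvaluation <- function(features, labels, spec = modelSpec(),
                                nBoot = 100L, eventId = NULL) {
    y <- .as01(labels)
    base <- splitData(y, spec$trainFrac, spec$seed)
    aurocs <- rep(NA_real_, nBoot)
    for (b in seq_len(nBoot)) {
        s <- spec
        s$seed <- seedSchedule(spec$seed, 2L, b)
        boot <- withSeed(s$seed,
                         sample(base$train, length(base$train),
                                replace = TRUE))
        if (length(unique(y[boot])) < 2L) next
        res <- tryCatch(trainEventModel(features, y, s,
                                        split = list(train = boot,
                                                     test = base$test),
                                        eventId = eventId),
                        error = function(e) NULL)
        if (!is.null(res)) aurocs[b] <- res$auroc
    }
    ok <- !is.na(aurocs)
    if (!any(ok)) stop("all bootstraps failed")
    structure(list(aurocs = aurocs, mean = mean(aurocs[ok]),
                   sd = if (sum(ok) > 1) sd(aurocs[ok]) else 0,
                   n = sum(ok), nFailed = sum(!ok), eventId = eventId,
                   algorithm = spec$algorithm),
              class = "AurocDistribution")
}
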