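Package: commfactor
Title: Cell-Cell Communication Inference from Single-Cell Expression by
    Matrix Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers directed, weighted cell-cell communication networks
    from a single-cell gene expression matrix alone, without
    ligand-receptor priors. The expression matrix A (genes x cells) is
    factorized as A = R * Sigma * W, where R is a gene regulatory network
    adjacency matrix (inferred by lasso projection plus lagged regression,
    or supplied by the user), Sigma is the singular-value matrix of A,
    and the cell-cell communication matrix W is solved with the
    Moore-Penrose pseudoinverse. Downstream tools aggregate W into
    cell-type communication networks with mean-threshold significance
    calls, nominate ligand-receptor pairs behind a given communication by
    sorted-expression correlation with Bonferroni control, benchmark
    inferred networks by ROC/AUC against literature or spatial ground
    truth, and simulate expression data with planted regulatory and
    communication structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    glmnet,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    SummarizedExperiment,
    pracma,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
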