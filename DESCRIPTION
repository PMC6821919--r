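Package: quenchfit
Title: Fluorescence Quenching Titration Analysis of Protein-Ligand Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising small-molecule binding to proteins from
    steady-state and time-resolved fluorescence titrations. Implements
    whole-spectrum inner-filter-effect correction, Stern-Volmer and double-log
    quenching analysis in intensity and band-area modes, Van't Hoff
    thermodynamic decomposition, the model-free interaction density function
    (IDF) method with Scatchard diagnostics and multi-class cooperative Hill
    fitting, multiexponential TCSPC decay fitting with intensity-weighted
    average lifetimes, and circular dichroism mean-residue-ellipticity
    conversion. A ground-truthed synthetic-data generator reproduces the
    statistical structure of a tryptophan-quenching titration (cooperative
    static quenching plus ligand inner-filter attenuation) for validation and
    method development.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'spectrum-methods.R'
    'spectra-ops.R'
    'quenching.R'
    'thermodynamics.R'
    'idf.R'
    'timeresolved.R'
    'cd.R'
    'io.R'
    'synthetic.R'
    'pipeline.R'
    'quenchfit-package.R'
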