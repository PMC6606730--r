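Package: emofuse
Title: Multimodal Emotion-Intensity Recognition by Choquet-Integral Fusion
    of EEG and Eye-Movement Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dual five-level classification of emotional arousal and valence
    from multichannel EEG and eye-movement recordings. Implements frame
    blocking with Hamming windowing, linear-phase FIR band-pass filtering,
    band power-spectral (APS), band energy (AE) and hemispheric-asymmetry
    (DAPS) features, Infomax ICA spatial filter banks with validity
    judgment and SVD spatial features, eye-movement event statistics and
    pupil features with illumination removal, anchor-based stimulus
    selection from normalized rating scores, and decision-level fusion of
    per-modality support-vector classifiers by the discrete Choquet
    integral with fuzzy measures learned by quadratic programming. A
    synthetic-data generator emulates class-conditioned multimodal trials
    so the full pipeline is testable without recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
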