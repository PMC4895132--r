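Package: mammocad
Title: Mammographic Lesion Discrimination with Stacked Denoising
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative characterization and benign/malignant
    classification of mammographic lesions. Computes 15 microcalcification
    shape/intensity descriptors, 26 mass shape and gray-level co-occurrence
    (Haralick) texture descriptors and their 41-feature combination from
    grayscale images with binary lesion masks; classifies the resulting
    feature vectors with a stacked denoising autoencoder (greedy layer-wise
    pretraining, softmax top layer, supervised fine-tuning) and benchmarks
    it against SVM, k-nearest-neighbour and linear discriminant analysis
    under an accuracy/sensitivity/specificity/AUC protocol with stratified
    10-fold cross-validation. Includes a synthetic lesion phantom generator
    and feature-table simulator with ground truth for end-to-end testing,
    plus simple top-hat and Otsu plumbing detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    EBImage,
    e1071,
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    MASS,
    class,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
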