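{"seed":1,"outputDir":"painAU_output","simulation":{"nSubjects":140,"segmentSeconds":20,"durationJitter":0.15,"frameRate":25,"topologyId":"mesh478","noiseSd":0.01,"poseRotSD":2,"poseTransSD":0.02,"subjectShapeSd":0.02,"gainSd":0.1,"distractorProb":0.15,"backgroundProb":0.3,"seed":1872770567},"augmentation":{"enableFlip":true,"rotationRange":15,"translationRange":0.05,"scaleRange":null,"shearRange":0.1,"seed":1006937113},"au_detector":{"inputSize":null,"hiddenUnits":128,"outputUnits":8,"batchSize":64,"maxEpochs":500,"learningRate":0.01,"adamBeta1":0.9,"adamBeta2":0.999,"threshold":0.5,"patience":0,"seed":1934158203},"intensity":{"inputSize":null,"hiddenUnits":128,"outputUnits":8,"batchSize":64,"maxEpochs":500,"learningRate":0.01,"adamBeta1":0.9,"adamBeta2":0.999,"threshold":0.5,"patience":0,"seed":659038654},"pain_transformer":{"naInput":8,"projectionDim":1024,"numHeads":4,"numLayers":2,"ffDim":null,"mlpHidden":256,"dropout":0.1,"learningRate":1e-05,"batchSize":16,"maxEpochs":150,"adamBeta1":0.9,"adamBeta2":0.999,"seed":1757345855},"pain_lstm":{"naInput":8,"numLayers":2,"hiddenDim":512,"learningRate":0.001,"batchSize":16,"maxEpochs":150,"adamBeta1":0.9,"adamBeta2":0.999,"seed":938043931},"evaluation":{"kAU":3,"kPain":10,"windowLength":350,"stride":null,"tailFrac":0.4,"frameStride":1,"auSource":"ground8","seed":1266554053}}
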