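method,metric,AU6,AU10,AU12,AU14,AU17
majority_class,rmse,1.68,1.87,1.93,0.54,0.58
majority_class,mae,1.08,1.42,1.40,0.21,0.17
random_guess,rmse,2.57,2.36,2.43,2.90,2.95
random_guess,mae,2.07,1.90,1.96,2.36,2.42
image_resnet50,rmse,0.57,0.61,0.60,0.64,0.50
image_resnet50,mae,0.49,0.51,0.48,0.14,0.12
landmark_fcn,rmse,0.72,0.72,0.75,0.52,0.57
landmark_fcn,mae,0.61,0.60,0.63,0.20,0.16
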