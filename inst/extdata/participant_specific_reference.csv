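participant,svm_train_acc,svm_test_acc,svm_test_auc,cnn_train_acc,cnn_test_acc,cnn_test_auc
P1,1.000,0.957,0.941,0.965,0.900,0.767
P2,0.998,0.997,1.000,0.987,0.972,0.850
P3,0.998,0.952,0.992,0.970,0.800,0.822
P5,0.999,0.984,0.904,0.998,0.974,0.915
P6,0.996,0.989,0.996,0.978,0.951,0.886
P7,0.997,0.920,0.970,0.829,0.720,0.826
P8,0.993,0.945,0.983,0.944,0.895,0.835
P10,0.994,0.984,0.878,0.990,0.982,0.856
P12,0.950,0.920,0.941,0.971,0.842,0.828
P13,1.000,0.996,0.964,0.994,0.956,0.888
P14,0.997,0.839,0.929,0.981,0.718,0.760
P15,0.998,0.972,0.978,0.948,0.889,0.918
P16,1.000,0.954,0.992,0.767,0.903,0.966
P18,0.992,0.939,0.981,0.958,0.935,0.941
P19,1.000,1.000,1.000,0.831,0.885,0.789
P20,1.000,0.995,0.995,0.990,0.982,0.856
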