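id,role,smiles,ic50_uM,pic50_reported
D1,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(F)C=C2,0.88,0.081
D2,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(Cl)C=C2,1.87,-0.134
D3,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(Br)C=C2,2.39,-0.34
D4,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(C)C=C2,0.54,0.47
D5,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(OC)C=C2,0.09,1.15
D6,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(O)C=C2,0.19,0.523
D7,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C([N+](=O)[O-])C=C2,3.09,-0.49
D8,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=CC=C2F,5.28,-0.72
D9,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=CC=C2Cl,3.99,-0.59
D10,train,NC(=S)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=CC=C2Br,4.44,-0.62
D11,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(F)C=C2,6.64,-0.8
D12,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(Cl)C=C2,7.54,-0.8
D13,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(Br)C=C2,6.77,-0.84
D14,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(C)C=C2,7.68,-0.87
D15,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(OC)C=C2,5.88,-0.76
D16,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(O)C=C2,5.33,-0.72
D17,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C([N+](=O)[O-])C=C2,7.89,-0.89
D18,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=CC=C2F,6.66,-0.82
D19,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=CC=C2Cl,7.32,-0.86
D20,train,NC(=S)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=CC=C2Br,6.56,-0.81
D21,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C(F)C=C2,8.99,-0.95
D22,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C(Cl)C=C2,8.26,-0.91
D23,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C(Br)C=C2,10.09,-1.0
D24,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C(C)C=C2,9.88,-0.94
D25,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C(OC)C=C2,8.19,-0.91
D26,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C(O)C=C2,11.24,-1.1
D27,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=C([N+](=O)[O-])C=C2,10.77,-1.03
D28,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=CC=C2F,13.48,-2.53
D29,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=CC=C2Cl,12.35,-1.135
D30,train,NC(=S)N1N=C(C2=CC(Br)=C(Br)C=C2)CC1C2=CC=CC=C2Br,11.09,-1.042
F1,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(F)C=C2,18.45,-1.26
F2,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(Cl)C=C2,16.16,-1.21
F3,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(Br)C=C2,18.47,-1.27
F4,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(C)C=C2,19.34,-1.28
F5,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=C(OC)C=C2,17.21,-1.2
F6,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=CC=C2Cl,24.21,-1.38
F7,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC=CC=C2,28.71,-1.46
F8,test,CC(=O)N1N=C(C2=CC(Cl)=C(Cl)C=C2)CC1C2=CC(OC)=CC(OC)=C2,25.52,-1.41
F9,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(F)C=C2,15.61,-1.2
F10,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(Cl)C=C2,19.74,-1.3
F11,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(Br)C=C2,20.64,-1.31
F12,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(C)C=C2,17.52,-1.24
F13,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=C(OC)C=C2,15.34,-1.18
F14,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=CC=C2Cl,21.48,-1.33
F15,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC=CC=C2,20.06,-1.3
F16,test,CC(=O)N1N=C(C2=CC(C)=C(C)C=C2)CC1C2=CC(OC)=CC(OC)=C2,17.33,-1.24
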