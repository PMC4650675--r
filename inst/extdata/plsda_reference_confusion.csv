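phase,true_class,Albic Luvisols,Haplic Luvisols,Chernozems,Eutric Cambisols,Phaeozems
Training,Albic Luvisols,24,0,0,0,0
Training,Haplic Luvisols,0,48,0,0,0
Training,Chernozems,0,0,19,0,0
Training,Eutric Cambisols,0,0,0,30,0
Training,Phaeozems,0,0,0,0,32
LOO,Albic Luvisols,21,0,0,0,3
LOO,Haplic Luvisols,0,48,0,0,0
LOO,Chernozems,1,3,12,0,3
LOO,Eutric Cambisols,0,1,0,28,1
LOO,Phaeozems,0,2,3,0,27
Testing,Albic Luvisols,12,0,0,0,0
Testing,Haplic Luvisols,1,15,0,6,2
Testing,Chernozems,0,0,9,0,1
Testing,Eutric Cambisols,0,2,0,13,0
Testing,Phaeozems,1,0,0,0,15
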