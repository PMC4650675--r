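phase,true_class,Albic Luvisols,Haplic Luvisols,Chernozems,Eutric Cambisols,Phaeozems
Training,Albic Luvisols,23,0,0,0,1
Training,Haplic Luvisols,0,48,0,0,0
Training,Chernozems,0,1,18,0,0
Training,Eutric Cambisols,0,0,0,30,0
Training,Phaeozems,0,1,0,0,31
LOO,Albic Luvisols,21,2,0,0,1
LOO,Haplic Luvisols,0,47,0,0,1
LOO,Chernozems,1,2,15,0,1
LOO,Eutric Cambisols,0,1,0,29,0
LOO,Phaeozems,0,1,2,0,29
Testing,Albic Luvisols,12,0,0,0,0
Testing,Haplic Luvisols,1,20,0,3,0
Testing,Chernozems,0,0,10,0,0
Testing,Eutric Cambisols,0,0,0,15,0
Testing,Phaeozems,0,0,1,0,15
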