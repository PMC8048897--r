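tree_id,species,dob_cm,bt_max_cm,bt_f_cm
t1,Eucalyptus crebra,28.3,3.1,2.1
t2,Eucalyptus albens,20.3,1.0,0.9
t3,Callitris glaucophylla,25.4,1.1,1.0
t4,Allocasuarina luehmannii,28.0,0.9,0.8
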