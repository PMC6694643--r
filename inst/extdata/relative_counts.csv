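group,relative_class,n_total,n_affected
control,parent,570,203
control,sibling,704,217
control,offspring,440,33
control,paternal_sibling,791,123
control,maternal_sibling,740,107
control,paternal_cousin,176,14
control,maternal_cousin,825,97
case,parent,583,314
case,sibling,670,332
case,offspring,419,67
case,paternal_sibling,802,168
case,maternal_sibling,770,148
case,paternal_cousin,175,32
case,maternal_cousin,934,142
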