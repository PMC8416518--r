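decision_variable,enumeration,n_classes,random_rate,success_rate,gain,accuracy,macro_precision,macro_recall
agreement_reached,"Yes now|No",2,50.00,60.14,1.2028,60.14,78.06,69.78
discount_settlement,"0|15|20|25|30|35|40|45|50|55|60|65|70|75|80",15,6.67,46.74,7.0075,46.74,61.18,58.71
installments,"1|2|3|4|5|6",6,16.67,56.06,3.3629,56.06,69.97,68.08
installments_paid,"0|1|2|3|4",5,20.00,49.86,2.4930,49.86,68.11,60.75
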