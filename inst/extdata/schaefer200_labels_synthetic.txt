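7Networks_LH_Vis_Striate_1
7Networks_LH_Vis_ExStr_1
7Networks_LH_Vis_Striate_2
7Networks_LH_Vis_ExStr_2
7Networks_LH_Vis_Striate_3
7Networks_LH_Vis_ExStr_3
7Networks_LH_Vis_Striate_4
7Networks_LH_Vis_ExStr_4
7Networks_LH_Vis_Striate_5
7Networks_LH_Vis_ExStr_5
7Networks_LH_Vis_Striate_6
7Networks_LH_Vis_ExStr_6
7Networks_LH_Vis_Striate_7
7Networks_LH_Vis_ExStr_7
7Networks_LH_Vis_Striate_8
7Networks_LH_SomMot_Cent_1
7Networks_LH_SomMot_Aud_1
7Networks_LH_SomMot_Cent_2
7Networks_LH_SomMot_Aud_2
7Networks_LH_SomMot_Cent_3
7Networks_LH_SomMot_Aud_3
7Networks_LH_SomMot_Cent_4
7Networks_LH_SomMot_Aud_4
7Networks_LH_SomMot_Cent_5
7Networks_LH_SomMot_Aud_5
7Networks_LH_SomMot_Cent_6
7Networks_LH_SomMot_Aud_6
7Networks_LH_SomMot_Cent_7
7Networks_LH_SomMot_Aud_7
7Networks_LH_SomMot_Cent_8
7Networks_LH_SomMot_Aud_8
7Networks_LH_SomMot_Cent_9
7Networks_LH_DorsAttn_Post_1
7Networks_LH_DorsAttn_FEF_1
7Networks_LH_DorsAttn_Post_2
7Networks_LH_DorsAttn_FEF_2
7Networks_LH_DorsAttn_Post_3
7Networks_LH_DorsAttn_FEF_3
7Networks_LH_DorsAttn_Post_4
7Networks_LH_DorsAttn_FEF_4
7Networks_LH_DorsAttn_Post_5
7Networks_LH_DorsAttn_FEF_5
7Networks_LH_DorsAttn_Post_6
7Networks_LH_DorsAttn_FEF_6
7Networks_LH_DorsAttn_Post_7
7Networks_LH_SalVentAttn_ParOper_1
7Networks_LH_SalVentAttn_FrMed_1
7Networks_LH_SalVentAttn_ParOper_2
7Networks_LH_SalVentAttn_FrMed_2
7Networks_LH_SalVentAttn_ParOper_3
7Networks_LH_SalVentAttn_FrMed_3
7Networks_LH_SalVentAttn_ParOper_4
7Networks_LH_SalVentAttn_FrMed_4
7Networks_LH_SalVentAttn_ParOper_5
7Networks_LH_SalVentAttn_FrMed_5
7Networks_LH_SalVentAttn_ParOper_6
7Networks_LH_SalVentAttn_FrMed_6
7Networks_LH_Limbic_OFC_1
7Networks_LH_Limbic_TempPole_1
7Networks_LH_Limbic_OFC_2
7Networks_LH_Limbic_TempPole_2
7Networks_LH_Limbic_OFC_3
7Networks_LH_Limbic_TempPole_3
7Networks_LH_Cont_Par_1
7Networks_LH_Cont_PFCl_1
7Networks_LH_Cont_Par_2
7Networks_LH_Cont_PFCl_2
7Networks_LH_Cont_Par_3
7Networks_LH_Cont_PFCl_3
7Networks_LH_Cont_Par_4
7Networks_LH_Cont_PFCl_4
7Networks_LH_Cont_Par_5
7Networks_LH_Cont_PFCl_5
7Networks_LH_Cont_Par_6
7Networks_LH_Cont_PFCl_6
7Networks_LH_Cont_Par_7
7Networks_LH_Cont_PFCl_7
7Networks_LH_Cont_Par_8
7Networks_LH_Default_PFC_1
7Networks_LH_Default_PCC_1
7Networks_LH_Default_Temp_1
7Networks_LH_Default_PFC_2
7Networks_LH_Default_PCC_2
7Networks_LH_Default_Temp_2
7Networks_LH_Default_PFC_3
7Networks_LH_Default_PCC_3
7Networks_LH_Default_Temp_3
7Networks_LH_Default_PFC_4
7Networks_LH_Default_PCC_4
7Networks_LH_Default_Temp_4
7Networks_LH_Default_PFC_5
7Networks_LH_Default_PCC_5
7Networks_LH_Default_Temp_5
7Networks_LH_Default_PFC_6
7Networks_LH_Default_PCC_6
7Networks_LH_Default_Temp_6
7Networks_LH_Default_PFC_7
7Networks_LH_Default_PCC_7
7Networks_LH_Default_Temp_7
7Networks_LH_Default_PFC_8
7Networks_RH_Vis_Striate_1
7Networks_RH_Vis_ExStr_1
7Networks_RH_Vis_Striate_2
7Networks_RH_Vis_ExStr_2
7Networks_RH_Vis_Striate_3
7Networks_RH_Vis_ExStr_3
7Networks_RH_Vis_Striate_4
7Networks_RH_Vis_ExStr_4
7Networks_RH_Vis_Striate_5
7Networks_RH_Vis_ExStr_5
7Networks_RH_Vis_Striate_6
7Networks_RH_Vis_ExStr_6
7Networks_RH_Vis_Striate_7
7Networks_RH_Vis_ExStr_7
7Networks_RH_Vis_Striate_8
7Networks_RH_SomMot_Cent_1
7Networks_RH_SomMot_Aud_1
7Networks_RH_SomMot_Cent_2
7Networks_RH_SomMot_Aud_2
7Networks_RH_SomMot_Cent_3
7Networks_RH_SomMot_Aud_3
7Networks_RH_SomMot_Cent_4
7Networks_RH_SomMot_Aud_4
7Networks_RH_SomMot_Cent_5
7Networks_RH_SomMot_Aud_5
7Networks_RH_SomMot_Cent_6
7Networks_RH_SomMot_Aud_6
7Networks_RH_SomMot_Cent_7
7Networks_RH_SomMot_Aud_7
7Networks_RH_SomMot_Cent_8
7Networks_RH_SomMot_Aud_8
7Networks_RH_SomMot_Cent_9
7Networks_RH_DorsAttn_Post_1
7Networks_RH_DorsAttn_FEF_1
7Networks_RH_DorsAttn_Post_2
7Networks_RH_DorsAttn_FEF_2
7Networks_RH_DorsAttn_Post_3
7Networks_RH_DorsAttn_FEF_3
7Networks_RH_DorsAttn_Post_4
7Networks_RH_DorsAttn_FEF_4
7Networks_RH_DorsAttn_Post_5
7Networks_RH_DorsAttn_FEF_5
7Networks_RH_DorsAttn_Post_6
7Networks_RH_DorsAttn_FEF_6
7Networks_RH_DorsAttn_Post_7
7Networks_RH_SalVentAttn_ParOper_1
7Networks_RH_SalVentAttn_FrMed_1
7Networks_RH_SalVentAttn_ParOper_2
7Networks_RH_SalVentAttn_FrMed_2
7Networks_RH_SalVentAttn_ParOper_3
7Networks_RH_SalVentAttn_FrMed_3
7Networks_RH_SalVentAttn_ParOper_4
7Networks_RH_SalVentAttn_FrMed_4
7Networks_RH_SalVentAttn_ParOper_5
7Networks_RH_SalVentAttn_FrMed_5
7Networks_RH_SalVentAttn_ParOper_6
7Networks_RH_SalVentAttn_FrMed_6
7Networks_RH_Limbic_OFC_1
7Networks_RH_Limbic_TempPole_1
7Networks_RH_Limbic_OFC_2
7Networks_RH_Limbic_TempPole_2
7Networks_RH_Limbic_OFC_3
7Networks_RH_Limbic_TempPole_3
7Networks_RH_Cont_Par_1
7Networks_RH_Cont_PFCl_1
7Networks_RH_Cont_Par_2
7Networks_RH_Cont_PFCl_2
7Networks_RH_Cont_Par_3
7Networks_RH_Cont_PFCl_3
7Networks_RH_Cont_Par_4
7Networks_RH_Cont_PFCl_4
7Networks_RH_Cont_Par_5
7Networks_RH_Cont_PFCl_5
7Networks_RH_Cont_Par_6
7Networks_RH_Cont_PFCl_6
7Networks_RH_Cont_Par_7
7Networks_RH_Cont_PFCl_7
7Networks_RH_Cont_Par_8
7Networks_RH_Default_PFC_1
7Networks_RH_Default_PCC_1
7Networks_RH_Default_Temp_1
7Networks_RH_Default_PFC_2
7Networks_RH_Default_PCC_2
7Networks_RH_Default_Temp_2
7Networks_RH_Default_PFC_3
7Networks_RH_Default_PCC_3
7Networks_RH_Default_Temp_3
7Networks_RH_Default_PFC_4
7Networks_RH_Default_PCC_4
7Networks_RH_Default_Temp_4
7Networks_RH_Default_PFC_5
7Networks_RH_Default_PCC_5
7Networks_RH_Default_Temp_5
7Networks_RH_Default_PFC_6
7Networks_RH_Default_PCC_6
7Networks_RH_Default_Temp_6
7Networks_RH_Default_PFC_7
7Networks_RH_Default_PCC_7
7Networks_RH_Default_Temp_7
7Networks_RH_Default_PFC_8
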